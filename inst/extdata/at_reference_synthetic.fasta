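># synthetic AT reference | constructed stand-in profile for signature extraction (not a natural sequence)
HKPWQYERWREINTGQCFCIPIGCNSQHRQYADITGGWMGMRQHMHAMRMGRILINKISC
NNNDIIMLPQYDHNHPKYVRCCRVNSHTKGHSQGVGMDTYVPDECHKIMTQKSFHMVCYS
SPVQLCYGEDLKWSCCIMIGVPWLAHPIHDEHQMDVNNFHDFWRAAVPGNPWAFFAHSMH
SYEFLPHLPAYTRYAFHSFYSKFMFPMHETLFVWPQGLILRDESLILKGIQCEWFMPVVL
AIDLIPVQFAMTPSETGRSLTESGNQEHRRPIWHVPEANLFQCHRKFNYARYGCQEYILC
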