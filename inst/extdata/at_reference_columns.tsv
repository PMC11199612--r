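# 24 marked active-site columns (0-based) of the packaged synthetic AT reference.
# The column set is a constructed stand-in keyed to at_reference_synthetic.fasta;
# substitute your own reference FASTA + column file to use a published profile.
column
58
62
88
89
91
92
93
95
97
116
118
147
150
152
170
193
194
196
197
199
221
224
250
253
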