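# Universal segments appended to the target-specific 40-mer (total 61 bases):
# a read-primer segment and the complement of the P7 lawn primer. Override by
# passing your own file to universal_segments().
universal_mid: GATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATC
p7_complement: ATCTCGTATGCCGTCTTCTGCTTG
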