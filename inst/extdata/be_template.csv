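name,sequence,contig,position,orientation,edit_type,ref,alt,mode
example_snv_revert,,chr1,4750,+,substitution,C,T,revert
example_snv_install,ACTGGCTTAAGCATTCGATACCAGTTAGCTTAGGCTAATCGGATCGATTACGGCTAGCTAACTGGTATCGAATGCTTAAGCCAGT,,13,+,substitution,A,G,install
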