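name,sequence,contig,position,orientation,edit_type,ref,alt,pbs_len,rtt_len,mode
example_snv_raw,ACTGGCTTAAGCATTCGATACCAGTTAGCTTAGGCTAATCGGATCGATTACGGCTAGCTAACTGGTATCGAATGCTTAAGCCAGTACTGGCTTAAGCATTCGATACCAGTTAGCTTAGGCTAATCGGATCGATTACGGCTAGCTAACTGGTATCGAATGCTTAAGCCAGTACTGGCTTAAGCATTCGATACCAGTTAGCTTAGGCTAATCGGATCGATTACGGCTAGCTAACTG,,118,+,substitution,G,T,13,13,install
example_ins_genomic,,chr1,4750,+,insertion,-,CTT,13,13,install
example_del_revert,,chr1,9820,+,deletion,ACG,-,13,16,revert
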