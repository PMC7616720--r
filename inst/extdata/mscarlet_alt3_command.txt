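python3 SpliceNouveau.py --initial_cds ATGGCGAGAACAATGGTTGCTATGGTGTCCAAGGGTGAAGCAGTCATAAAGGAGTTTATGAGGTTCAAGGTGCACATGGAAGGGTCAATGAACGGACATGAGTTCGAAATTGAAGGGGAGGGCGAGGGCCGCCCCTATGAAGGGACACAAACTGCCAAGCTCAAGGTAACCAAGGGGGGACCCCTACCATTCTCATGGGACATTCTGTCCCCGCAATTCATGTATGGTTCTCGTGCATTCACAAAGCATCCTGCTGATATCCCAGACTACTACAAACAATCCTTTCCGGAGGGCTTTAAGTGGGAACGCGTCATGAATTTCGAGGACGGAGGCGCGGTGACGGTCACTCAAGATACCAGCCTAGAGGACGGCACGCTTATTTACAAAGTCAAGCTACGCGGAACGAACTTCCCTCCCGATGGGCCGGTCATGCAAAAGAAAACAATGGGGTGGGAGGCGTCGACCGAGCGCTTGTACCCCGAGGACGGAGTACTAAAGGGAGATATAAAGATGGCATTGCGCCTAAAAGACGGGGGACGATACCTGGCCGACTTCAAGACCACCTACAAGGCCAAGAAGCCCGTGCAGATGCCCGGCGCCTACAACGTGGACCGAAAGCTGGACATCACCAGCCACAACGAGGACTACACCGTGGTGGAGCAGTACGAGAGGAGCGAGGGCAGGCACAGCACCGGCGGCATGGACGAGCTGTACAAGGACTACAAGGACGATGATGACAAA --initial_intron1 GTaagNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNNTGTGTGTGTGTGTGTGTGTGAATGTGTGTGTGTGTGTGTGNcAG --ce_start 216 --ce_end 216 --five_utr CGGCCGCTTCTTGGTGCCAGCTTATCAtagcgctaccggtcgccacc --three_utr TAATAAACAAATGGTaagGAAGGGCACATCAATCTTTGCTTAATTGTCCTTTACTCTAAAGATGTATTTTATCATACTGAATGCTAAACTTGATATCTCCTTTTAGGTCATTGATGTCCTTCACCCCGGGAAGGCGACAGTGCCTAAGACAGAAATTCGGGAAAAACTAGCCAAAATGTACAAGACCACACCGGATGTCATCTTTGTATTTGGATTCAGAACTCAGTAAACTGGATCCGCAGGCCTCTGCTAGCTTGACTGACTGAGATACAGCGTACCTTCAGCTCACAGACATGATAAGATACATTGATGAGTTTGGACAAACCACAACTAGAATGCAGTGAAAAAAATGCTTTATTTGTGAAATTTGTGATGCTATTGCTTTATTTGTAACCATTATAAGCTGCAATAAACAAGTTAACAACAACAATTGCATTCATTTTATGTTTCAGGTTCAGGGGGAGGTGTGGGAGGTTTTTTAA --ignore_end 470 --aa generate_it --upstream_mut_chance 0.3 --downstream_mut_chance 1 -a 30 --intron1_mut_chance 0.5 -n 3000 --cds_mut_start_trim 160 --cds_mut_end_trim 396 --overwrite --ce_score_weight 3 --early_stop 500 --target_const_donor 1 --target_const_acc 0.5 --intron1_mut_chance 0.5 --alt_3p --overwrite --alt_position in_exon --alt_3p_end_trim 471 --downstream_mut_n 1 --target_cryptic_acc 0.75 --min_alt_dist 40 --track_splice_scores
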