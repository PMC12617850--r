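name,fragment_formula,loss_formula,ion_type,provenance
N5-hydroxyornithine,C5H10N2O2,C5H10N2O2,protonated,inferred
N5-formyl-N5-hydroxyornithine,C6H8N2O3,C6H10N2O3,protonated,inferred
hexanoyl-C6H10O2,C6H10O2,C6H10O2,protonated,reported
C4H7NO,C4H7NO,C4H7NO,protonated,reported
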