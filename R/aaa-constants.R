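# Shared constants. Coordinates are 0-based half-open throughout the package;
# conversion to 1-based happens only when writing VCF.

BASES <- c("A", "C", "G", "T")

# Observation classes used by pileup counting and the genotype vocabulary.
# 1..4 = A,C,G,T; 5 = insertion (anchored); 6 = deletion.
CLASS_LABELS <- c("A", "C", "G", "T", "I", "D")
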