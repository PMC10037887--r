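# loaded first (collation order): shared constants
DNA_BASES <- c("A", "C", "G", "T")

# substitution alternatives: column b = the three bases != DNA_BASES[b]
SUB_ALT <- vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b), character(3))
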