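## data.table non-standard evaluation columns
utils::globalVariables(c(
    ".", ".N", "bin", "matchedSite", "expected", "matched", "score",
    "group", "grp", "ngroup", "chrom", "pos", "alt", "strain", "win",
    "N", "start", "end", "percent", "normalized", "reads", "d",
    "l2", "w", "sample"))

.datatable.aware <- TRUE
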