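## independent rule-table oracles for the allele-state classifiers,
## transcribed clause by clause with explicit precedence

krasOracle <- function(vaf, cr) {
    if (vaf < 0.05) return("absent")
    if (vaf >= 0.05 && vaf < 0.4) return("dGD")
    if (vaf >= 0.4 && vaf < 0.61) return("HET")
    if (vaf >= 0.61 && cr >= 1.3 && cr < 2.8) return("gain")
    if (vaf >= 0.61 && cr >= 2.8) return("amp")
    if (vaf >= 0.61 && cr < 1.3) return("LOH")
    stop("unreachable")
}

cdkn2aOracle <- function(vaf, cr) {
    if (vaf >= 0.85 || cr <= 0.19) return("HOM")
    if ((vaf > 0 && vaf < 0.85) || (cr > 0.19 && cr < 0.87)) return("HET")
    if (vaf == 0 && cr >= 0.87) return("WT")
    stop("unreachable")
}
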