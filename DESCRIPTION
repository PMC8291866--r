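Package: gcmeta
Title: Meta-Analysis of Case-Control Genotype Counts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic-association meta-analysis from study-level
    genotype counts. Builds the five classical genetic-model contrasts
    (allelic, heterozygous, homozygous, dominant, recessive) as 2x2
    tables, estimates per-study odds ratios with Woolf standard errors,
    pools them by Mantel-Haenszel or inverse-variance fixed effects and
    DerSimonian-Laird random effects with a Cochran Q-driven selection
    rule, screens control genotypes for Hardy-Weinberg equilibrium
    (chi-square and exact tests), stratifies by ethnicity, control source
    and phenotype, runs leave-one-out sensitivity analysis and the
    Begg-Mazumdar rank-correlation test for publication bias, and
    simulates genotype-count study sets under a multiplicative per-allele
    odds model for calibration checks. Ships the CDKN2B-AS1 rs1333049 and
    rs4977574 coronary heart disease study table as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), metafor, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
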