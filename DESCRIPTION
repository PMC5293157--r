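Package: promdecon
Title: Dissecting Global and Specific Transcriptional Regulation from
    Promoter Activity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to decompose bacterial promoter activity measured across
    environmental conditions into a growth-rate-coupled global component and
    a transcription-factor-mediated specific component, and to infer the
    regulatory metabolites (and their transcription factors) that explain the
    specific component. Includes quantification of promoter activity and
    growth rate from plate-reader GFP/OD600 time courses, singular value
    decomposition of the log-normalized activity matrix, no-intercept
    regression of the specific component against metabolome profiles with
    AIC-based single-versus-pair model comparison, hypergeometric enrichment
    of transcription-factor targets, leave-one-condition-out cross-validation,
    and a synthetic-data generator emulating the statistical structure of
    such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
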