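Package: puparia
Title: Landmark Morphometrics and Discriminant Identification of Blow Fly
    Puparia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying calliphorid (blow fly) puparia from
    landmark coordinates digitized on the posterior spiracular plates.
    Implements the full analysis pipeline: extraction of 27 morphometric
    variables (slit lengths, slit angles, plate widths, derived totals,
    ratios and means, plus two scored qualitative characters) from twelve
    user-digitized points; dichotomous pre-filtering on diagnostic
    qualitative characters; stepwise canonical discriminant analysis with
    partial R-square entry and removal tests; canonical discriminant
    analysis with the four standard multivariate test statistics (Wilks'
    Lambda, Pillai's trace, Hotelling-Lawley trace, Roy's greatest root)
    and their F approximations; linear-discriminant classification with
    resubstitution error; and a probability rule for multi-specimen
    identifications.  A synthetic-data module generates grouped feature
    tables from published per-taxon summary statistics and synthesizes
    landmark configurations realizing prescribed feature values, so the
    whole pipeline is testable without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
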