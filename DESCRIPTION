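Package: faerspv
Title: Disproportionality Analysis of FAERS-Style Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection on spontaneous
    adverse-event reports in the layout of the FDA Adverse Event Reporting
    System (FAERS) quarterly files. Reads the DEMO/DRUG/REAC/OUTC/INDI/THER
    tables ("$"-delimited ASCII or CSV), assembles and deduplicates case
    reports, selects drug-event cohorts by MedDRA Preferred Term and
    primary-suspect drug role, and computes four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio,
    information component, empirical Bayes geometric mean) with their
    published decision criteria. Also provides time-to-onset analysis,
    descriptive demographic and outcome tables, overdose/suicide-subset dose
    summaries, complication rankings, and a synthetic spontaneous-report
    generator with planted relative risk for validating every stage without
    access to the real database. Ships a default configuration for
    ibuprofen- and acetaminophen-associated kidney injury.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
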