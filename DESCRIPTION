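Package: dtdt
Title: Dosage Transmission/Disequilibrium Test for Trios with Inferred Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Family-based association testing when some trio members carry
    only posterior genotype probabilities ("dosages") rather than hard calls.
    Implements the dosage Transmission/Disequilibrium Test (dTDT), which
    generalizes the classic TDT pseudo-counts of transmitted and
    non-transmitted alleles to expected transmissions under a trio's dosage
    probabilities; an exact enumeration-based genotype posterior for
    un-genotyped parents in nuclear families; a disease-model trio simulator
    (dominant, recessive, co-dominant; prevalence, penetrances, and linkage
    disequilibrium to the tested SNP); the case-control allele-count test and
    its Mantel-Haenszel combination with the dTDT; common genetic-map
    construction from microsatellite anchors with marker-cleaning rules; and
    readers/writers for LINKAGE/MERLIN-style pedigree, map, and dosage files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
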