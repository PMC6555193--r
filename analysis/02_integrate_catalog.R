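#!/usr/bin/env Rscript
# Integrate compound source records into a unique-compound catalog via the
# five-key identity scheme (name / SMILES / InChIKey / PubChem CID / CAS)
# and scrub natural products that match the drug exclusion list.

suppressPackageStartupMessages(library(npnet))
stopifnot(dir.exists("results/scenario"))

sc <- load_scenario("results/scenario")
merged <- merge_compounds(sc$compounds)
scrubbed <- scrub_drugs(merged$catalog, sc$exclusion)

dir.create("results/catalog", showWarnings = FALSE)
write_catalog(list(catalog = scrubbed$catalog, conflicts = merged$conflicts),
              "results/catalog/catalog.tsv",
              "results/catalog/conflicts.tsv")
write.table(scrubbed$removed, "results/catalog/removed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d source records -> %d unique compounds (%d NP, %d CT)",
                nrow(sc$compounds), nrow(merged$catalog),
                sum(merged$catalog$class == "NP"),
                sum(merged$catalog$class == "CT")))
message(sprintf("%d key conflicts flagged; %d NP compounds scrubbed as drugs",
                nrow(merged$conflicts), nrow(scrubbed$removed)))
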