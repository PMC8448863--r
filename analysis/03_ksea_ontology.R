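#!/usr/bin/env Rscript
# Kinase-substrate enrichment (KSEA) and ontology over-representation on
# the differential results of analysis/02. KSEA groups sites significant at
# raw p < 0.05 into kinase substrate sets, tests up- and down-regulated
# directions separately by upper-tail hypergeometric, applies pooled BH,
# and scores each kinase's fold-change shift as a z-score classified at
# +/- 1.5. Ontology terms are tested the same way over protein identifiers.

suppressMessages(library(marrowniche))
dir.create("results", showWarnings = FALSE)

if (!file.exists("results/phospho_differential.tsv"))
  stop("run analysis/02_phospho_differential.R first")
diff <- read_tsv("results/phospho_differential.tsv")
setdb <- read_gmt("results/phospho_kinase_sets.gmt")

ks <- ksea(diff, setdb, sig_p = 0.05)
write_tsv(ks, "results/ksea.tsv")
top <- ks[order(ks$p), ][1:5, c("set", "direction", "k", "K", "n", "N",
                                "enrichment_factor", "p", "q", "z", "class")]
cat("top KSEA rows:\n"); print(top, row.names = FALSE, digits = 3)
cat(sprintf("kinases called over/under-represented at |z| >= 1.5: %d / %d\n",
            sum(ks$class != "neutral", na.rm = TRUE) %/% 2L,
            length(unique(ks$set))))

# ontology-style ORA: planted "terms" from the generator truth, universe =
# all tested sites
truth <- read_tsv("results/phospho_truth.tsv")
universe <- diff$peptide_id[!is.na(diff$p)]
hits <- diff$peptide_id[!is.na(diff$p) & diff$p < 0.05]
terms <- setdb[grepl("^decoy", names(setdb))][1:10]
terms$planted_programme <- truth$peptide_id[!is.na(truth$kinase)]
ora <- ontology_enrichment(hits, universe, terms)
ora <- ora[order(ora$p), ]
write_tsv(ora, "results/ontology_enrichment.tsv")
cat(sprintf("planted programme term: p = %.3g, q = %.3g, enrichment %.2f\n",
            ora$p[ora$set == "planted_programme"],
            ora$q[ora$set == "planted_programme"],
            ora$enrichment_factor[ora$set == "planted_programme"]))
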