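#!/usr/bin/env Rscript
# Sliding-window Hudson Fst (50 kb windows, 10 kb steps) between the three
# case ponies and the 24-sample control pool, 99th-percentile thresholding,
# and overlap of the selected windows with the shared ROH regions.

suppressMessages(library(miniscan))
out_dir <- "results/fst"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

gm <- read_vcf("results/sim/population.vcf")
cases <- paste0("case_", 1:3)
controls <- paste0("control_", 1:24)

fw <- windowed_fst(gm, cases, controls, window_bp = 50000, step_bp = 10000)
write.table(fw, file.path(out_dir, "fst_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("computed %d windows (%d informative)\n",
            nrow(fw), sum(is.finite(fw$fst))))

top <- top_percentile(fw, q = 0.99)
cat(sprintf("99th-percentile threshold: Fst >= %.3f; %d windows selected\n",
            top$threshold, nrow(top$selected)))
merged <- merge_selected_windows(top$selected)
cat(sprintf("selected windows merge into %d regions\n", nrow(merged)))
write.table(top$selected, file.path(out_dir, "top_windows.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bed(merged, file.path(out_dir, "top_regions.bed"))

shared <- read_bed("results/roh/shared_regions.bed")
ov <- overlap_with_roh(top$selected, shared)
write.table(ov, file.path(out_dir, "fst_roh_overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nshared ROH regions hit by top-percentile Fst windows:\n")
print(ov, row.names = FALSE)
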