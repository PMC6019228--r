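#!/usr/bin/env Rscript
# Build the synthetic study population every later step analyses: 3 case
# ponies vs 24 pooled controls on two autosomes, with
#   - a 500 kb autozygous tract shared by all three cases on chr1 (plus one
#     private tract per case), emulating the shared-ROH selection signature,
#   - a divergent-frequency block inside the shared tract (case 0.95 /
#     control 0.05) for the Fst scan,
#   - a narrow case-exclusive block (case 1.0 / control 0.0) providing
#     hom-mut-in-cases / hom-wt-in-controls candidate variants,
# and an annotation table marking two of the exclusive variants as
# HIGH/MODERATE effect (SIFT-style scores 0.00 and 0.07).
# Writes VCF + TSV truth tables under results/sim/.

suppressMessages(library(miniscan))
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cases <- paste0("case_", 1:3)
shared <- data.frame(chrom = "1", start = 4.0e6, end = 4.5e6)
private <- data.frame(sample_id = cases,
                      chrom = c("1", "2", "2"),
                      start = c(7.2e6, 1.0e6, 3.1e6),
                      end = c(7.6e6, 1.45e6, 3.5e6))
planted <- rbind(
  data.frame(sample_id = rep(cases, each = 1), chrom = shared$chrom,
             start = shared$start, end = shared$end),
  private)

cfg <- sim_config(
  n_cases = 3, n_controls = 24,
  chrom_lengths = c(`1` = 10e6, `2` = 5e6),
  planted_roh = planted,
  divergent_loci = data.frame(
    chrom = c("1", "1"),
    start = c(4.10e6, 4.150e6),
    end = c(4.30e6, 4.155e6),
    case_freq = c(0.95, 1.0),
    control_freq = c(0.05, 0.0)),
  seed = 20180625)

gm <- simulate_genotypes(cfg)
write_vcf(gm, file.path(out_dir, "population.vcf"))
write.table(planted, file.path(out_dir, "truth_planted_roh.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cfg$divergent_loci, file.path(out_dir, "truth_divergent.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# annotation table: the exclusive block's variants get HIGH/MODERATE effect
# (one deleterious, one tolerated), everything else LOW/MODIFIER
v <- gm$variants
excl <- which(v$chrom == "1" & v$pos >= 4.150e6 & v$pos <= 4.155e6)
set.seed(20180625)
ann <- data.frame(chrom = v$chrom, pos = v$pos, alt = v$alt,
                  effect_class = sample(c("LOW", "MODIFIER"), nrow(v), TRUE),
                  sift_score = NA_real_, gene = NA_character_,
                  stringsAsFactors = FALSE)
stopifnot(length(excl) >= 2)
ann$effect_class[excl[1]] <- "HIGH"
ann$sift_score[excl[1]] <- 0.00
ann$gene[excl[1]] <- "ADAMTS17"
ann$effect_class[excl[2]] <- "MODERATE"
ann$sift_score[excl[2]] <- 0.07
ann$gene[excl[2]] <- "OSTN"
write.table(ann, file.path(out_dir, "annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("samples:", length(gm$sample_ids), "  variants:", nrow(v), "\n")
cat("planted shared tract: chr1:", shared$start, "-", shared$end, "\n")
cat("case-exclusive candidate variants at chr1:",
    paste(v$pos[excl], collapse = ", "), "\n")
cat("wrote", file.path(out_dir, "population.vcf"), "and truth tables\n")
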