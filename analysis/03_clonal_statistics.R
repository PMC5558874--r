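#!/usr/bin/env Rscript
# Clonal statistics over the called clone tables: richness versus dose,
# serial-transplant persistence of dominant clones, multi-organ sharing,
# Nei's G between spleen parts versus spleen-femur (spatial drift), and the
# gain from pooling bone-marrow samples. Writes tables under results/tables/.

suppressPackageStartupMessages(library(clonetrack))

rep_dir <- "results/reports"
out_dir <- "results/tables"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
sheet <- read.delim("results/run/sample_sheet.tsv")

load_clones <- function(sid) {
  df <- read.delim(file.path(rep_dir, paste0("clones_", sid, ".tsv")))
  setNames(df$frequency, df$tag)
}
clones <- lapply(setNames(sheet$sample_id, sheet$sample_id), load_clones)
primaries <- sheet[sheet$generation == 1 & sheet$organ == "spleen_p1", ]

# --- richness versus transplant dose (primary spleens) ---------------------
rich <- data.frame(mouse = primaries$mouse_id,
                   dose = primaries$barcoded_cells,
                   richness = vapply(clones[primaries$sample_id], length, 0L))
write.table(rich[order(rich$dose), ], file.path(out_dir, "dose_richness.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Mean recovered barcodes by dose (primary spleens):")
print(tapply(rich$richness, rich$dose, mean))

# --- serial-transplant persistence of dominant (>1%) clones ----------------
per_rows <- list()
for (i in seq_len(nrow(primaries))) {
  lin <- primaries$lineage_id[i]
  kids <- sheet[sheet$lineage_id == lin & sheet$generation == 2 &
                  grepl("spleen", sheet$organ), "sample_id"]
  if (!length(kids)) next
  p <- persistence(clones[[primaries$sample_id[i]]], clones[kids])
  per_rows[[lin]] <- data.frame(lineage = lin, dose = primaries$barcoded_cells[i],
                                n_dominant = p$n_dominant,
                                n_detected = p$n_detected,
                                fraction = p$fraction)
}
per <- do.call(rbind, per_rows)
write.table(per, file.path(out_dir, "persistence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "Persistence: %d/%d dominant primary clones re-detected in secondaries",
  sum(per$n_detected), sum(per$n_dominant)))

# --- multi-organ sharing of dominant spleen clones -------------------------
share_rows <- list()
for (i in seq_len(nrow(primaries))) {
  m <- primaries$mouse_id[i]
  organs <- c("femur_L", "femur_R", "meninges")
  sh <- site_sharing(clones[[primaries$sample_id[i]]],
                     setNames(clones[paste(m, organs, sep = "_")], organs))
  share_rows[[m]] <- data.frame(mouse = m, dose = primaries$barcoded_cells[i],
                                t(sh))
}
share <- do.call(rbind, share_rows)
write.table(share, file.path(out_dir, "site_sharing.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Mean detected fraction of dominant spleen clones per organ:")
print(colMeans(share[, c("femur_L", "femur_R", "meninges")]))

# --- spatial drift: G within spleen vs spleen-femur ------------------------
g_rows <- list()
for (i in seq_len(nrow(primaries))) {
  m <- primaries$mouse_id[i]
  g_sp <- nei_G(clones[paste(m, c("spleen_p1", "spleen_p2"), sep = "_")])$G
  g_fem <- nei_G(clones[paste(m, c("spleen_p1", "femur_L"), sep = "_")])$G
  g_rows[[m]] <- data.frame(mouse = m, dose = primaries$barcoded_cells[i],
                            G_spleen_parts = g_sp, G_spleen_femur = g_fem)
}
gtab <- do.call(rbind, g_rows)
write.table(gtab, file.path(out_dir, "diversity_G.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "Median G: spleen part vs part %.4f; spleen vs injected femur %.4f",
  median(gtab$G_spleen_parts), median(gtab$G_spleen_femur)))

# --- pooling bone-marrow samples recovers more barcodes --------------------
pool_rows <- list()
for (i in seq_len(nrow(primaries))) {
  m <- primaries$mouse_id[i]
  bones <- clones[paste(m, c("femur_L", "femur_R"), sep = "_")]
  pr <- pooled_richness(bones)
  pool_rows[[m]] <- data.frame(mouse = m, dose = primaries$barcoded_cells[i],
                               mean_single_bone = mean(pr$per_sample),
                               pooled = pr$union)
}
pool <- do.call(rbind, pool_rows)
write.table(pool, file.path(out_dir, "pooled_bone_richness.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "Pooled bones recover %.1f barcodes on average vs %.1f per single bone",
  mean(pool$pooled), mean(pool$mean_single_bone)))
message("Tables written under ", out_dir)
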