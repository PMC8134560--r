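#!/usr/bin/env Rscript
# Step 5 -- k-shell decomposition, occupancy histograms, group SSE.
#
# Decomposes each subject's voxel network, normalizes shell indices by
# the subject's k_max, pools nodes per group, bins them into 15
# normalized-shell bins per module, and compares the module histograms
# between every pair of groups by the sum of squared errors.

suppressPackageStartupMessages(library(flnet))

subjects <- readRDS("scratch/cohort_networks.rds")
acfg <- analysis_config(n_null = 500, seed = 20260101L)
hash <- config_hash(acfg)
mods <- c("pre-SMA", "BA(L)", "v-preMA(L)", "WA(L)")

groups <- split(names(subjects), sub("_s[0-9]+$", "", names(subjects)))
shell_rows <- list()
hists <- list()
for (gname in names(groups)) {
  assigns <- list()
  for (sid in groups[[gname]]) {
    res <- subjects[[sid]]
    if (is.null(res$voxel_net)) next
    sa <- kshell_decomposition(res$voxel_net)
    assigns[[sid]] <- sa
    shell_rows[[sid]] <- data.frame(
      subject = sid, group = gname, voxel = res$nodes$index,
      module = res$nodes$region, k_s = sa$shell, k_max = sa$k_max,
      normalized = sa$shell / sa$k_max)
  }
  hists[[gname]] <- occupancy_histogram(assigns, group = gname,
                                        n_bins = acfg$n_bins,
                                        modules = mods)
  top <- vapply(hists[[gname]]$modules, function(m)
    if (is.null(m)) NA_real_ else m$mass[15], numeric(1))
  cat(sprintf("%-18s last-bin occupancy: %s\n", gname,
              paste(sprintf("%s %.2f", names(top), top), collapse = ", ")))
}
write_tsv(do.call(rbind, shell_rows), "results/05_shells.tsv", hash)

hist_tab <- do.call(rbind, lapply(hists, function(h)
  do.call(rbind, lapply(names(h$modules), function(m) {
    x <- h$modules[[m]]
    if (is.null(x)) return(NULL)
    data.frame(group = h$group, module = m, bin = seq_len(h$n_bins),
               lower = (seq_len(h$n_bins) - 1) / h$n_bins,
               mass = x$mass, count = x$counts)
  }))))
write_tsv(hist_tab, "results/05_occupancy_histograms.tsv", hash)

sse <- sse_between_groups(hists)
write_tsv(sse, "results/05_sse.tsv", hash)
cat("\nSSE by module and group pair:\n")
print(sse, row.names = FALSE)
cat("\nAll SSE values are small: the cohort's groups share the planted\n",
    "attachment physiology (they differ only in WA prevalence, and the\n",
    "pooled histograms count WA-active subjects only). Step 06 runs the\n",
    "paired WA-coupling contrast where the occupancy difference lives.\n")

pdf("results/05_occupancy.pdf", width = 7, height = 9)
plot_occupancy(hists, modules = mods)
dev.off()
cat("wrote results/05_shells.tsv, 05_occupancy_histograms.tsv, 05_sse.tsv,",
    "05_occupancy.pdf\n")
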