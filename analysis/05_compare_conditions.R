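#!/usr/bin/env Rscript
# Paired REST-vs-HUT comparison of the causality networks: per-link Wilcoxon
# signed rank tests on the subject-wise estimates, Benjamini-Hochberg FDR
# within each estimator's 12 links, direction from the median difference.
# The synthetic shift raises M->H (baroreflex) and R->M, C->M, and halves the
# respiratory drive R->H and the H->C influence, so those links should flag.

library(ctenet)

for (est in c("mb", "mf")) {
  rest_f <- sprintf("results/links_%s_rest.csv", est)
  hut_f <- sprintf("results/links_%s_hut.csv", est)
  if (!file.exists(rest_f) || !file.exists(hut_f)) {
    cat(sprintf("[%s] link tables missing, run 03/04 first\n", est))
    next
  }
  cmp <- compare_networks(read.csv(rest_f), read.csv(hut_f))
  write.csv(cmp, sprintf("results/comparison_%s.csv", est), row.names = FALSE)
  cat(sprintf("\n%s REST vs HUT (BH-corrected, q = 0.05):\n", toupper(est)))
  print(cmp[order(cmp$p), ], digits = 3)
}
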