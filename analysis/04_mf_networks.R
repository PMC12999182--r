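#!/usr/bin/env Rscript
# Model-free conditional transfer entropy networks: non-uniform embedding
# (L=10, k=10) per link, per subject and condition. This is the long-running
# path: per-subject time-shift surrogate significance re-selects the embedding
# for every surrogate, so this driver runs the estimates for the full cohort
# but the per-subject significance pass at desk scale: REST condition only,
# the first 8 subjects, 40 outer surrogates, 15 admission shuffles inside
# surrogate replicates. The full-scale settings (both conditions, 20 subjects,
# 100 surrogates, Ns = 100) take hours on one core; raise the constants below
# to reproduce them.

library(ctenet)

Ns_embed <- 50L      # admission shuffles for the reported estimates
n_surr <- 40L        # outer time-shift surrogates in the significance pass
sig_subjects <- 8L   # subjects entering the desk-scale significance pass
sig_conditions <- "rest"

cohort <- read_cohort("results/data")
dag <- zero_lag_dag()

for (cond in c("rest", "hut")) {
  pre <- lapply(cohort, function(sub) highpass_detrend(sub[[cond]]))
  nets <- lapply(seq_along(pre), function(i) {
    mf_network(pre[[i]], dag, Ns = Ns_embed, seed = 4100L + i)
  })
  links <- collect_links(nets)
  write.csv(links, sprintf("results/links_mf_%s.csv", cond), row.names = FALSE)
  cat(sprintf("\nMF %s: mean T per link (nats)\n", toupper(cond)))
  print(aggregate(estimate ~ source + target, links, mean), digits = 3)

  if (!cond %in% sig_conditions) next
  sig <- lapply(seq_len(sig_subjects), function(i) {
    network_significance("mf", pre[[i]],
                         surrogate_config(n_surr, method = "time_shift",
                                          seed = 4600L + i),
                         dag, mf_params = list(Ns = 15L))
  })
  deg <- significance_summary(sig)
  write.csv(deg, sprintf("results/significance_mf_%s.csv", cond), row.names = FALSE)
  print(deg, digits = 3)
}
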