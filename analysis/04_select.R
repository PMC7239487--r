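# Stage 4: minimum-redundancy maximum-relevance feature selection.
#
# Greedy mRMR on the pooled training windows per wear site, constrained to
# the 10, 15 and 20 best features. The k sets are nested by construction;
# reports mirror the published feature-table structure.

source("analysis/00_config.R")

train_tab <- as.data.frame(data.table::fread(
  file.path(results_dir, "features_train.csv")))
candidates <- intersect(feature_catalog(), names(train_tab))

for (site in sites) {
  st <- train_tab[train_tab$site == site, ]
  for (k in k_list) {
    sel <- mrmr_select(st[, candidates], st$ee_kcal_min, k = k)
    data.table::fwrite(
      data.frame(rank = seq_len(sel$k), feature = sel$ordered_features,
                 relevance = sel$relevance[sel$ordered_features],
                 step_score = sel$step_scores,
                 step_redundancy = sel$step_redundancy),
      file.path(results_dir, sprintf("selection_%s_k%d.csv", site, k)))
  }
  top <- mrmr_select(st[, candidates], st$ee_kcal_min, k = 5)
  message(sprintf("%s top 5: %s", site,
                  paste(top$ordered_features, collapse = ", ")))
}
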