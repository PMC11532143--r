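# shared fixture builders and small oracles

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

# three-series toy batch on a regular online grid
make_toy_batch <- function(id = "toy") {
  batch_dataset(
    batch_meta(id, strain = "S1", medium = "M9",
               operation_conditions = list(t_set = 37)),
    list(ferm_ts("ph", seq(0, 10, by = 0.5), 7 - 0.01 * seq(0, 10, by = 0.5),
                 source = "online"),
         ferm_ts("co2_out", c(0.2, 3, 6.1, 9.4), c(1, 1.5, 2, 2.2),
                 source = "at_line", unit = "%"),
         ferm_ts("biomass", c(0, 4, 8), c(0.2, 1.1, 6), source = "offline",
                 unit = "OD600")))
}

# independent Spearman oracle: explicit average ranks, then textbook
# Pearson formula on the ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Jaccard index between an injected interval and the union of flagged
# intervals overlapping it
interval_jaccard <- function(inj, ivs) {
  ov <- ivs[ivs$end > inj[1] & ivs$start < inj[2], , drop = FALSE]
  if (!nrow(ov)) return(0)
  inter <- sum(pmin(ov$end, inj[2]) - pmax(ov$start, inj[1]))
  union <- sum(ov$end - ov$start) + (inj[2] - inj[1]) - inter
  inter / union
}

subset_samples_for_test <- function(s, idx) fermfuse:::subset_samples(s, idx)
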