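# In-code fixtures: small spot volume tables built programmatically.

# A fully crossed table: k spots x n_reps replicates x both channels for one
# group, with deterministic volumes.
make_group_table <- function(k = 3, n_reps = 4, group = "DFD",
                             pr = rep(0.5, k), base = 1000) {
  spots <- sprintf("S%03d", seq_len(k))
  grid <- expand.grid(spot = seq_len(k), replicate = seq_len(n_reps))
  tot <- data.frame(spot_id = spots[grid$spot], group = group,
                    replicate = grid$replicate, channel = "total",
                    volume = base * grid$spot + 10 * grid$replicate,
                    stringsAsFactors = FALSE)
  pho <- tot
  pho$channel <- "phospho"
  pho$volume <- tot$volume * pr[grid$spot]
  rbind(tot, pho)
}

# Drop a spot's rows on selected replicates (both channels) to emulate
# detection dropout.
drop_replicates <- function(tab, spot_id, replicates,
                            channels = c("total", "phospho")) {
  drop <- tab$spot_id == spot_id & tab$replicate %in% replicates &
    tab$channel %in% channels
  tab[!drop, , drop = FALSE]
}
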