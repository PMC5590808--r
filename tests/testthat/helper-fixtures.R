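# Shared in-code fixtures; no data files.

# transect table whose per-island species totals are exactly `totals`,
# spread over n_plots integer counts
transects_from_totals <- function(totals_koram, totals_nomsao, n_plots = 14) {
  spread <- function(total, n) {
    base <- rep(total %/% n, n)
    extra <- total %% n
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
    base
  }
  rows <- list()
  for (isl in c("Koram", "NomSao")) {
    totals <- if (isl == "Koram") totals_koram else totals_nomsao
    for (sp in names(totals)) {
      rows[[paste(isl, sp)]] <- data.frame(
        island = isl, transect_index = seq_len(n_plots), species = sp,
        count = spread(totals[[sp]], n_plots), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# minimal oyster-tool table: `weights` is a named list user_id -> weights,
# islands taken from the first character of the user id (K/N)
tools_from_users <- function(weights, task = "oyster") {
  rows <- lapply(names(weights), function(u) data.frame(
    island = if (startsWith(u, "K")) "Koram" else "NomSao",
    tool_id = paste0(u, "_", seq_along(weights[[u]])), task = task,
    weight_g = weights[[u]], user_id = u, user_class = "adult_male",
    provenance = "observed_use", stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# two-island prey size table with given per-island lengths (width = 0.6 len)
sizes_from_lengths <- function(koram, nomsao, taxon = "oyster") {
  data.frame(
    island = rep(c("Koram", "NomSao"), c(length(koram), length(nomsao))),
    taxon = taxon, length_mm = c(koram, nomsao),
    width_mm = 0.6 * c(koram, nomsao), stringsAsFactors = FALSE)
}
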