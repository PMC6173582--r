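# Synaptic-output fractions from a transcribed synapse-count table.

#' Read a synapse-count table
#'
#' Simple CSV with columns source, target, count (non-negative integers;
#' one row per connection class). The package ships a small table of
#' published synapse counts for the AS motor-neuron class and the A/B
#' MN classes under \code{inst/extdata/vnc_synapse_counts.csv}.
#'
#' @param path CSV path; default the bundled table.
#' @return data.frame(source, target, count).
#' @export
readSynapseTable <- function(path = system.file("extdata",
                                                "vnc_synapse_counts.csv",
                                                package = "undulaR")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "count") %in% names(tab)))
  if (any(tab$count < 0)) undulaError("negative synapse count", "inputError")
  if (anyDuplicated(tab[, c("source", "target")]))
    undulaError("duplicate (source, target) pair", "inputError")
  tab
}

#' Synaptic-output fractions of one source class
#'
#' Fraction of a source's outgoing synapses per target, with percentages
#' rounded half-up to whole numbers (the printed convention: 68 of 144
#' gives 47%, 66 of 144 gives 46%). Fractions sum to 1; rounded percents
#' sum to 100 within +/-1.
#'
#' @param table data.frame(source, target, count).
#' @param source source class (e.g. "AS").
#' @return data.frame(target, count, fraction, percent), descending count.
#' @export
synapseFractions <- function(table, source) {
  rows <- table[table$source == source, ]
  if (nrow(rows) == 0L)
    undulaError(sprintf("unknown source class '%s'", source), "lookupError")
  total <- sum(rows$count)
  if (total == 0L)
    undulaError("source has zero outgoing synapses", "undefinedError")
  out <- data.frame(target = rows$target, count = rows$count,
                    fraction = rows$count / total,
                    percent = roundHalfUp(100 * rows$count / total))
  out[order(-out$count), ]
}
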