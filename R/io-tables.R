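#' Construct a posterior state table
#'
#' The node x site x state probability array produced by ancestral state
#' reconstruction. For every (node, site) the state probabilities sum to 1
#' (within tolerance) unless `partial = TRUE` (used for residue tables whose
#' rows may carry separately-reported stop-codon mass).
#'
#' @param arr Numeric 3-d array with dimnames `(node, site, state)`.
#' @param partial Allow (node, site) rows summing to less than 1.
#' @return The array with class `posterior_table`.
#' @export
posterior_table <- function(arr, partial = FALSE) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  dn <- dimnames(arr)
  missing_dn <- if (is.null(dn)) dim(arr) > 0 else
    vapply(1:3, function(k) is.null(dn[[k]]) && dim(arr)[k] > 0, TRUE)
  if (any(missing_dn))   # zero-extent dims legitimately drop their names
    stop("posterior array needs full dimnames (node, site, state)")
  if (any(arr < -1e-12) || any(arr > 1 + 1e-9))
    stop("posterior probabilities must lie in [0, 1]")
  arr[arr < 0] <- 0
  sums <- apply(arr, c(1L, 2L), sum)
  if (partial) {
    if (any(sums > 1 + 1e-9)) stop("posterior rows must sum to at most 1")
  } else if (any(abs(sums - 1) > 1e-9)) {
    stop("posterior rows must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  }
  structure(arr, class = "posterior_table", partial = partial)
}

#' @export
print.posterior_table <- function(x, ...) {
  d <- dim(x)
  cat("<posterior_table> ", d[1L], " nodes x ", d[2L], " sites x ", d[3L],
      " states\n", sep = "")
  invisible(x)
}

pt_nodes <- function(x) dimnames(x)[[1L]]
pt_states <- function(x) dimnames(x)[[3L]]

#' Write a posterior table as TSV
#'
#' One row per (node, site, state) with probability > 0; probabilities are
#' printed at 8 decimals (contract: at least 6) so a read-back
#' reproduces them well within 1e-6. Tab
#' delimited, UTF-8, '.' decimal separator.
#'
#' @param table A `posterior_table`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_state_table <- function(table, path) {
  stopifnot(inherits(table, "posterior_table"))
  dn <- dimnames(table)
  if (any(dim(table) == 0L)) {
    df <- data.frame(node = character(), site = character(),
                     state = character(), probability = numeric())
  } else {
    df <- expand.grid(node = dn[[1L]], site = dn[[2L]], state = dn[[3L]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$probability <- as.vector(table)
    df <- df[df$probability > 0, , drop = FALSE]
  }
  df <- df[order(df$node, as.integer(df$site), df$state), , drop = FALSE]
  df$probability <- sprintf("%.8f", df$probability)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("node", "site", "state", "probability"),
                   collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Read a posterior table written by [write_state_table()]
#'
#' Rows absent from the file are zero-filled.
#'
#' @param path TSV path.
#' @param states Optional state order for the rebuilt array; defaults to the
#'   sorted states present in the file.
#' @return A `posterior_table` (rows may not sum exactly to 1 because of the
#'   finite printing precision; they are accepted within 1e-5 and
#'   renormalized).
#' @export
read_state_table <- function(path, states = NULL) {
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "character", "numeric"))
  if (!nrow(df)) stop("state table is empty")
  nodes <- unique(df$node)
  sites <- sort(unique(df$site))
  if (is.null(states)) states <- sort(unique(df$state))
  arr <- array(0, dim = c(length(nodes), length(sites), length(states)),
               dimnames = list(nodes, as.character(sites), states))
  idx <- cbind(match(df$node, nodes), match(df$site, sites),
               match(df$state, states))
  arr[idx] <- df$probability
  sums <- apply(arr, c(1L, 2L), sum)
  if (any(abs(sums - 1) > 1e-5))
    stop("state table rows deviate from probability 1 beyond print precision")
  arr <- sweep(arr, c(1L, 2L), sums, "/")
  posterior_table(arr)
}
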