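#' @title qPCR tables and efficiency-corrected expression ratios
#' @name qpcr
#' @description
#' Relative transcript quantification between a nitrogen-replete condition
#' (`Nplus`) and a nitrogen-fixing condition (`Nminus`). Each gene amplifies
#' by a factor `(1 + E)` per cycle, with `E` its fractional primer
#' efficiency in (0, 1]; the efficiency-corrected expression ratio of a
#' target normalized to a reference is
#' \deqn{R = (1+E_t)^{\Delta Ct_t} / (1+E_r)^{\Delta Ct_r}, \quad
#'       \Delta Ct = \overline{Ct}(N^+) - \overline{Ct}(N^-).}
#' `R > 1` means higher expression under nitrogen fixation. Multiple
#' reference genes are combined by the geometric mean of their
#' normalization factors.
NULL

#' Read a Ct table (TSV: gene, condition, replicate, ct)
#'
#' @param path path to a tab-separated Ct table; `condition` must be
#'   `Nplus` or `Nminus`, `ct` positive cycles.
#' @return data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(d))) stop("Ct table needs columns: ",
                                     paste(need, collapse = ", "))
  validate_ct_table(d)
}

validate_ct_table <- function(d) {
  if (!all(d$condition %in% c("Nplus", "Nminus")))
    stop("condition must be 'Nplus' or 'Nminus'")
  if (any(!is.finite(d$ct) | d$ct <= 0)) stop("Ct values must be positive")
  class(d) <- unique(c("ct_table", class(d)))
  d
}

#' Read primer efficiencies (TSV: gene, efficiency)
#' @param path path to a tab-separated efficiency table.
#' @return named numeric vector of efficiencies in (0, 1].
#' @export
read_efficiencies <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "efficiency") %in% names(d)))
    stop("efficiency table needs columns 'gene' and 'efficiency'")
  setNames(d$efficiency, d$gene)
}

mean_dct <- function(d, gene) {
  g <- d[d$gene == gene, , drop = FALSE]
  if (nrow(g) == 0L) stop("gene not in Ct table: ", gene)
  for (cond in c("Nplus", "Nminus"))
    if (!any(g$condition == cond))
      stop("gene ", gene, " has no replicates under ", cond)
  plus <- g$ct[g$condition == "Nplus"]
  minus <- g$ct[g$condition == "Nminus"]
  list(dct = mean(plus) - mean(minus),
       se = sqrt(ifelse(length(plus) > 1, stats::var(plus) / length(plus), 0) +
                   ifelse(length(minus) > 1, stats::var(minus) / length(minus), 0)))
}

#' Efficiency-corrected relative expression ratio
#'
#' @param table a `ct_table` data frame (see [read_ct_table()]).
#' @param target target gene name.
#' @param reference character vector of one or more control genes (combined
#'   by geometric mean).
#' @param efficiencies named numeric vector of fractional primer
#'   efficiencies in (0, 1], covering target and references.
#' @param simple_ddct if `TRUE`, ignore efficiencies and use the classic
#'   2^(-ddCt) method (equivalent to setting every E to 1).
#' @param conf confidence level for the replicate-noise interval on the
#'   ratio (normal approximation on the log scale).
#' @return object of class `fold_change`: list with `gene`, `ratio`
#'   (Nminus/Nplus relative expression), `direction`, `fold`
#'   (`max(ratio, 1/ratio)`), `ratio_lo`, `ratio_hi`.
#' @export
relative_ratio <- function(table, target, reference, efficiencies,
                           simple_ddct = FALSE, conf = 0.95) {
  table <- validate_ct_table(as.data.frame(table))
  genes <- c(target, reference)
  if (simple_ddct) efficiencies <- setNames(rep(1, length(genes)), genes)
  miss <- setdiff(genes, names(efficiencies))
  if (length(miss)) stop("no efficiency for: ", paste(miss, collapse = ", "))
  E <- efficiencies[genes]
  if (any(E <= 0 | E > 1)) stop("efficiencies must lie in (0, 1]")
  dt <- mean_dct(table, target)
  drefs <- lapply(reference, function(g) mean_dct(table, g))
  ref_terms <- mapply(function(g, dr) log(1 + E[[g]]) * dr$dct,
                      reference, drefs)
  # normalizing to the geometric mean of the reference factors
  log_ratio <- log(1 + E[[target]]) * dt$dct - mean(ref_terms)
  var_log <- (log(1 + E[[target]]) * dt$se)^2 +
    sum(mapply(function(g, dr) (log(1 + E[[g]]) * dr$se)^2,
               reference, drefs)) / length(reference)^2
  z <- qnorm(1 - (1 - conf) / 2)
  ratio <- exp(log_ratio)
  structure(list(gene = target, ratio = ratio,
                 direction = if (ratio >= 1) "increase" else "decrease",
                 fold = max(ratio, 1 / ratio),
                 ratio_lo = exp(log_ratio - z * sqrt(var_log)),
                 ratio_hi = exp(log_ratio + z * sqrt(var_log))),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("<fold_change> %s: ratio %.3g (%s, %.2g-fold) [%.3g, %.3g]\n",
              x$gene, x$ratio, x$direction, x$fold, x$ratio_lo, x$ratio_hi))
  invisible(x)
}
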