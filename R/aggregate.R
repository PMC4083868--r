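#' @title Consensus aggregation of subject groups
#'
#' @description
#' Aggregation collapses a group of subjects into one display row per
#' group. For every (variant, allele column) cell the bases of the group
#' members are tallied (missing calls excluded) and a consensus base is
#' chosen: the most frequent base for the `"maximum"` method, or the least
#' frequent *observed* base for the `"minimum"` method, with ties broken by
#' the fixed base order A < C < G < T. The consensus base's relative
#' frequency among the informative member calls is stored with the cell, as
#' an indication of how representative the base is. Paternal and maternal
#' allele columns are aggregated independently, so differences between the
#' two chromosomes survive aggregation. Aggregated rows are labelled
#' `"AGN"` followed by the number of aggregated individuals.
#'
#' @name aggregation
NULL

#' Build subject groups from a categorical annotation column
#'
#' One group per distinct label, in order of first appearance among the
#' matrix's subjects; members keep current matrix order. Subjects with an
#' absent value join no group (their count is reported in a message).
#'
#' @param M a [hap_matrix].
#' @param meta a subject-axis [meta_table].
#' @param column name of a categorical column.
#' @return a named list of integer subject-index vectors, one per label.
#' @export
group_by_meta <- function(M, meta, column) {
  stopifnot(inherits(M, "hap_matrix"), inherits(meta, "meta_table"))
  if (meta_kind(meta, column) != "categorical") {
    stop("grouping requires a categorical column; bin numerical ",
         "annotations into categories first", call. = FALSE)
  }
  vals <- meta_values(meta, column, M$subject_ids)
  n_absent <- sum(is.na(vals))
  if (n_absent > 0L) {
    message("group_by_meta: ", n_absent,
            " subject(s) without a '", column, "' value form no group")
  }
  labels <- unique(vals[!is.na(vals)])
  groups <- lapply(labels, function(l) which(!is.na(vals) & vals == l))
  names(groups) <- labels
  groups
}

#' Consensus base and frequency of one cell
#'
#' @param bases character vector of member calls at one (variant, allele
#'   column) cell; `NA` entries (missing calls) are excluded from the tally.
#' @param method `"maximum"` (most frequent base) or `"minimum"` (least
#'   frequent observed base).
#' @return list with `consensus` (base or `NA` if all calls missing),
#'   `frequency` (consensus count / informative count; `NA` if none), and
#'   `n_informative`.
#' @examples
#' consensus_cell(c("A", "A", "A", "T"), "maximum")  # A, 0.75
#' consensus_cell(c("A", "A", "A", "T"), "minimum")  # T, 0.25
#' @export
consensus_cell <- function(bases, method = c("maximum", "minimum")) {
  method <- match.arg(method)
  if (length(bases) == 0L) {
    stop("consensus of an empty member set is undefined", call. = FALSE)
  }
  obs <- bases[!is.na(bases)]
  if (length(obs) == 0L) {
    return(list(consensus = NA_character_, frequency = NA_real_,
                n_informative = 0L))
  }
  counts <- tabulate(match(obs, ALLELE_BASES), nbins = 4L)
  present <- which(counts > 0L)
  pick <- if (method == "maximum") {
    present[which.max(counts[present])]
  } else {
    present[which.min(counts[present])]
  }
  list(consensus = ALLELE_BASES[pick],
       frequency = counts[pick] / length(obs),
       n_informative = length(obs))
}

#' Aggregate subject groups into consensus rows
#'
#' @param M a [hap_matrix].
#' @param groups named list of subject-index vectors (see
#'   [group_by_meta()]); groups must be disjoint and non-empty.
#' @param method `"maximum"` or `"minimum"` (see [consensus_cell()]).
#' @return an object of class `agg_matrix` with fields:
#'   `groups` (data frame: `name`, `label` = `AGN<k>`, `n_members`),
#'   `members` (list of subject-id vectors), `consensus` / `frequency` /
#'   `n_informative` (group x variant x allele-column arrays), `variants`,
#'   `method`, `phased`, `n_allele_columns`. The source matrix is
#'   unchanged.
#' @export
aggregate_rows <- function(M, groups, method = c("maximum", "minimum")) {
  stopifnot(inherits(M, "hap_matrix"))
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) == 0L) {
    stop("groups must be a non-empty list of subject-index vectors",
         call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named", call. = FALSE)
  }
  idx_all <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(idx_all)) {
    stop("groups overlap: every subject may belong to at most one group",
         call. = FALSE)
  }
  groups <- lapply(groups, check_indices, n = M$n_subjects, what = "subject")
  if (any(lengths(groups) == 0L)) {
    stop("empty groups are not allowed", call. = FALSE)
  }

  g <- length(groups); m <- M$n_variants; p <- M$n_allele_columns
  consensus <- array(NA_character_, dim = c(g, m, p))
  frequency <- array(NA_real_, dim = c(g, m, p))
  n_inf <- array(0L, dim = c(g, m, p))
  for (gi in seq_len(g)) {
    if (m == 0L) break
    calls <- hap_calls(M, subjects = groups[[gi]])
    counts <- vapply(ALLELE_BASES, function(b)
      apply(`dim<-`(as.numeric(calls == b), dim(calls)),
            c(2L, 3L), sum, na.rm = TRUE),
      matrix(0, nrow = m, ncol = p))           # m x p x 4
    counts <- array(counts, dim = c(m, p, 4L))
    inf <- apply(counts, c(1L, 2L), sum)
    pick <- apply(counts, c(1L, 2L), function(cnt) {
      present <- which(cnt > 0L)
      if (!length(present)) return(NA_integer_)
      if (method == "maximum") present[which.max(cnt[present])]
      else present[which.min(cnt[present])]
    })
    sel <- !is.na(pick)
    cons <- matrix(NA_character_, m, p)
    freq <- matrix(NA_real_, m, p)
    cons[sel] <- ALLELE_BASES[pick[sel]]
    cnt_sel <- counts[cbind(row(pick)[sel], col(pick)[sel], pick[sel])]
    freq[sel] <- cnt_sel / inf[sel]
    consensus[gi, , ] <- cons
    frequency[gi, , ] <- freq
    n_inf[gi, , ] <- inf
  }

  storage.mode(n_inf) <- "integer"
  structure(
    list(
      groups = data.frame(
        name = names(groups),
        label = paste0("AGN", lengths(groups)),
        n_members = lengths(groups),
        stringsAsFactors = FALSE),
      members = lapply(groups, function(ix) M$subject_ids[ix]),
      consensus = consensus,
      frequency = frequency,
      n_informative = n_inf,
      variants = M$variants,
      method = method,
      phased = M$phased,
      n_allele_columns = p
    ),
    class = "agg_matrix"
  )
}

#' @export
print.agg_matrix <- function(x, ...) {
  cat(sprintf(
    "agg_matrix: %d group(s) x %d SNVs x %d allele column(s), method %s\n",
    nrow(x$groups), nrow(x$variants), x$n_allele_columns, x$method))
  cat(paste0("  ", x$groups$name, " (", x$groups$label, ")",
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.agg_matrix <- function(x) {
  c(nrow(x$groups), nrow(x$variants), x$n_allele_columns)
}

#' Aggregate one annotation column over group members
#'
#' Numerical columns support `"minimum"`, `"maximum"` and `"mean"`;
#' categorical columns support `"mode"` (most frequent label, ties broken
#' lexicographically). Absent values are excluded.
#'
#' @param values vector of member values (numeric or character).
#' @param kind `"numerical"` or `"categorical"`.
#' @param method aggregation method (see above).
#' @return a single summary value (`NA` if all values are absent).
#' @export
aggregate_meta_column <- function(values, kind = c("numerical", "categorical"),
                                  method = c("minimum", "maximum", "mean",
                                             "mode")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  ok_methods <- if (kind == "numerical") c("minimum", "maximum", "mean")
                else "mode"
  if (!method %in% ok_methods) {
    stop("method '", method, "' is not defined for ", kind,
         " data (use ", paste(ok_methods, collapse = "/"), ")",
         call. = FALSE)
  }
  v <- values[!is.na(values)]
  if (!length(v)) {
    return(if (kind == "numerical") NA_real_ else NA_character_)
  }
  switch(method,
         minimum = min(v),
         maximum = max(v),
         mean = mean(v),
         mode = {
           tab <- table(v)
           labs <- names(tab)[tab == max(tab)]
           sort(labs, method = "radix")[1L]
         })
}
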