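#' Pipeline configuration
#'
#' Validates the configuration of a full processing run: load one input
#' (VCF or IMPUTE2 triple) plus optional annotation files, apply SNV
#' filters in declared order, apply stable sorts, optionally aggregate by a
#' subject annotation column, render and export. Stage order is fixed:
#' load, filters, sorts, aggregate, render.
#'
#' @param vcf path to a VCF file (alternative to the IMPUTE2 triple).
#' @param impute2 named list/vector with `hap`, `legend`, `sample` paths.
#' @param subject_meta,variant_meta paths to two-header-line annotation
#'   files.
#' @param filters list of filter specs, each a list with `type`
#'   (`"region"`, `"ids"`, `"regex"`, `"freq_above"`, `"freq_below"`) and
#'   its arguments: `region` (string `chrom:start-end`), `ids`
#'   (character vector or path of one id per line), `pattern`, `threshold`.
#' @param sort_rows,sort_cols annotation column names to sort subjects /
#'   variants by (in order; each applied as one stable sort).
#' @param aggregate_by categorical subject annotation column to group by.
#' @param method aggregation method, `"maximum"` or `"minimum"`.
#' @param opts a [render_options()] list.
#' @param out output image path.
#' @param format image format (default: from `out`'s extension).
#' @param log path for the plain-text transformation log (optional).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, impute2 = NULL,
                            subject_meta = NULL, variant_meta = NULL,
                            filters = list(), sort_rows = character(0),
                            sort_cols = character(0), aggregate_by = NULL,
                            method = "maximum", opts = render_options(),
                            out = NULL, format = NULL, log = NULL) {
  if (is.null(vcf) == is.null(impute2)) {
    stop("exactly one input (vcf or impute2 triple) must be given",
         call. = FALSE)
  }
  if (!is.null(impute2) &&
      !all(c("hap", "legend", "sample") %in% names(impute2))) {
    stop("impute2 input needs named elements hap, legend, sample",
         call. = FALSE)
  }
  if (is.null(out)) stop("an output path (out) is required", call. = FALSE)
  if (!is.null(aggregate_by)) method <- match.arg(method,
                                                  c("maximum", "minimum"))
  for (f in filters) validate_filter_spec(f)
  stopifnot(inherits(opts, "render_options"))
  structure(list(vcf = vcf, impute2 = impute2,
                 subject_meta = subject_meta, variant_meta = variant_meta,
                 filters = filters, sort_rows = sort_rows,
                 sort_cols = sort_cols, aggregate_by = aggregate_by,
                 method = method, opts = opts, out = out,
                 format = format, log = log),
            class = "pipeline_config")
}

validate_filter_spec <- function(f) {
  if (!is.list(f) || is.null(f$type)) {
    stop("each filter spec must be a list with a 'type'", call. = FALSE)
  }
  switch(f$type,
    region = {
      if (is.null(f$region)) stop("region filter needs 'region'",
                                  call. = FALSE)
      parse_region(f$region)
    },
    ids = if (is.null(f$ids)) stop("id filter needs 'ids'", call. = FALSE),
    regex = if (is.null(f$pattern)) stop("regex filter needs 'pattern'",
                                         call. = FALSE),
    freq_above = ,
    freq_below = {
      t <- f$threshold
      if (is.null(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
        stop("frequency filter needs a threshold in [0, 1]", call. = FALSE)
      }
    },
    stop("unknown filter type: '", f$type, "'", call. = FALSE))
  invisible(f)
}

#' Run the full load/filter/sort/aggregate/render pipeline
#'
#' Executes the stages of a [pipeline_config()] in fixed order and appends
#' one line per transformation (with before/after dimensions) to the
#' transformation log. Any stage error aborts with the offending stage
#' named.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `matrix` (filtered/sorted [hap_matrix]),
#'   `aggregated` (`agg_matrix` or `NULL`), `canvas`, `out` (image path)
#'   and `log` (character vector of log lines).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(length(log_lines) + 1L, width = 2), ". ", ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dims <- function(M) paste0(M$n_subjects, "x", M$n_variants)

  ## load
  loaded <- stage("load", {
    if (!is.null(cfg$vcf)) {
      res <- read_vcf(cfg$vcf)
      list(M = res$matrix, vmeta_stub = res$variant_meta,
           src = cfg$vcf)
    } else {
      list(M = read_impute2(cfg$impute2[["hap"]], cfg$impute2[["legend"]],
                            cfg$impute2[["sample"]]),
           vmeta_stub = NULL, src = cfg$impute2[["hap"]])
    }
  })
  M <- loaded$M
  note("load: ", loaded$src, " -> ", dims(M), " (",
       if (M$phased) "phased" else "unphased", ")")
  smeta <- if (!is.null(cfg$subject_meta)) {
    stage("load", read_meta(cfg$subject_meta, "subject"))
  }
  vmeta <- if (!is.null(cfg$variant_meta)) {
    stage("load", read_meta(cfg$variant_meta, "variant"))
  } else loaded$vmeta_stub

  ## filters, in declared order
  for (f in cfg$filters) {
    before <- dims(M)
    M <- stage(paste0("filter:", f$type), switch(f$type,
      region = filter_region(M, f$region),
      ids = {
        ids <- f$ids
        if (length(ids) == 1L && file.exists(ids)) {
          ids <- read_lines_maybe_gz(ids)
          ids <- trimws(ids[nzchar(trimws(ids))])
        }
        filter_id_list(M, ids)
      },
      regex = filter_id_regex(M, f$pattern),
      freq_above = filter_frequency(M, f$threshold, "above"),
      freq_below = filter_frequency(M, f$threshold, "below")))
    note("filter ", f$type,
         switch(f$type, region = paste0(" ", f$region),
                regex = paste0(" '", f$pattern, "'"),
                freq_above = paste0(" > ", f$threshold),
                freq_below = paste0(" < ", f$threshold), ""),
         ": ", before, " -> ", dims(M))
  }

  ## sorts (stable; consecutive sorts compose into a compound key)
  for (col in cfg$sort_rows) {
    if (is.null(smeta)) {
      stop("pipeline stage 'sort' failed: sort_rows requires subject_meta",
           call. = FALSE)
    }
    M <- stage("sort", sort_rows_by_meta(M, smeta, col))
    note("sort rows by '", col, "': ", dims(M), " (stable)")
  }
  for (col in cfg$sort_cols) {
    if (is.null(vmeta)) {
      stop("pipeline stage 'sort' failed: sort_cols requires variant_meta",
           call. = FALSE)
    }
    M <- stage("sort", sort_columns_by_meta(M, vmeta, col))
    note("sort columns by '", col, "': ", dims(M), " (stable)")
  }

  ## aggregate
  agg <- NULL
  if (!is.null(cfg$aggregate_by)) {
    if (is.null(smeta)) {
      stop("pipeline stage 'aggregate' failed: aggregate_by requires ",
           "subject_meta", call. = FALSE)
    }
    agg <- stage("aggregate", {
      groups <- group_by_meta(M, smeta, cfg$aggregate_by)
      aggregate_rows(M, groups, cfg$method)
    })
    note("aggregate by '", cfg$aggregate_by, "' (", cfg$method, "): ",
         dims(M), " -> ", nrow(agg$groups), "x", nrow(agg$variants))
  }

  ## render + export
  target <- if (is.null(agg)) M else agg
  canvas <- stage("render",
                  render_matrix(target, subject_meta = smeta,
                                variant_meta = vmeta, opts = cfg$opts))
  stage("render", export_image(canvas, cfg$out, format = cfg$format))
  note("render ", cfg$opts$encoding, " -> ", cfg$out,
       " (", canvas$width, "x", canvas$height, " px)")

  if (!is.null(cfg$log)) writeLines(log_lines, cfg$log)
  invisible(list(matrix = M, aggregated = agg, canvas = canvas,
                 out = cfg$out, log = log_lines))
}

#' One-line summary of a loaded data set
#'
#' Reports the subject and SNV counts, the phasing flag, and the number of
#' meta-information types: subject annotations ("MI columns") and variant
#' annotations ("MI rows").
#'
#' @param M a [hap_matrix].
#' @param subject_meta,variant_meta optional [meta_table]s.
#' @return the summary string, invisibly; it is also printed.
#' @export
summarize_dataset <- function(M, subject_meta = NULL, variant_meta = NULL) {
  stopifnot(inherits(M, "hap_matrix"))
  txt <- sprintf("%d subjects, %d SNVs, %s, %d MI columns, %d MI rows",
                 M$n_subjects, M$n_variants,
                 if (M$phased) "phased" else "unphased",
                 n_meta(subject_meta), n_meta(variant_meta))
  cat(txt, "\n")
  invisible(txt)
}
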