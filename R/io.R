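#' Read a taxon-by-sample count table
#'
#' Expects a tab-delimited file whose first column holds pipe-delimited
#' lineages and whose remaining columns hold non-negative per-sample counts
#' (or relative abundances). The first column is renamed to `lineage`.
#'
#' @param path Path to a tab-delimited abundance matrix.
#' @return A tibble: `lineage` plus one numeric column per sample.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "lineage"
  tbl <- tibble::as_tibble(df)
  validate_count_table(tbl)
  tbl
}

#' Read per-sample metadata
#'
#' @param path Tab-delimited file with at least the columns `sample_id`,
#'   `subject`, `visit`, `body_site`, `dataset`; any further columns are kept
#'   as covariates.
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- tibble::as_tibble(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
  need <- c("sample_id", "subject", "visit", "body_site", "dataset")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md
}

#' Read a BIOM-format abundance table
#'
#' Maps the observation metadata field `taxonomy` onto pipe-delimited
#' lineages. Requires the `biomformat` package.
#'
#' @param path Path to a BIOM file.
#' @return A count tibble as from [read_count_table()].
#' @export
read_biom_counts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("read_biom_counts() requires the 'biomformat' package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  mat <- as(biomformat::biom_data(b), "matrix")
  om <- biomformat::observation_metadata(b)
  lineage <- if (!is.null(om) && "taxonomy" %in% names(om)) {
    vapply(om[["taxonomy"]], function(x) paste(x[nzchar(x)], collapse = "|"),
           character(1))
  } else if (is.data.frame(om)) {
    apply(om, 1, function(x) paste(x[nzchar(x) & !is.na(x)], collapse = "|"))
  } else {
    rownames(mat)
  }
  tibble::as_tibble(cbind(
    tibble::tibble(lineage = unname(lineage)),
    as.data.frame(mat, check.names = FALSE)
  ))
}

validate_count_table <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (names(counts)[1] != "lineage") {
    stop("first column must be `lineage`", call. = FALSE)
  }
  parse_lineage(counts$lineage)
  if (anyDuplicated(counts$lineage)) {
    stop("duplicate lineages in count table", call. = FALSE)
  }
  vals <- count_values(counts)
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop("sample columns must be numeric", call. = FALSE)
  }
  if (any(as.matrix(vals) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  invisible(counts)
}

count_values <- function(counts) counts[, -1, drop = FALSE]

count_matrix <- function(counts) {
  m <- as.matrix(count_values(counts))
  rownames(m) <- counts$lineage
  m
}

#' Drop taxa without minimal sequence support
#'
#' A taxon is retained iff at least `min_samples` samples each contain at
#' least `min_count` of its sequences (default: two sequences in two
#' samples).
#'
#' @param counts A count tibble (`lineage` + sample columns).
#' @param min_count Minimum per-sample count for a sample to support a
#'   taxon.
#' @param min_samples Minimum number of supporting samples.
#' @return The filtered count tibble.
#' @export
filter_rare_taxa <- function(counts, min_count = 2, min_samples = 2) {
  validate_count_table(counts)
  stopifnot(min_count >= 1, min_samples >= 1)
  m <- count_matrix(counts)
  keep <- rowSums(m >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Flag suspect samples by top-taxon support
#'
#' For each sample, find its most abundant taxon `m` and compare the
#' sample's count of `m` to the maximum count of `m` across all samples. A
#' sample is flagged when its top taxon carries fewer than `frac` of the
#' sequences seen for that taxon in the sample where it peaks; all-zero
#' samples are flagged with their own reason code.
#'
#' @param counts A count tibble.
#' @param frac Fraction of the taxon's global maximum below which the
#'   sample is suspect (default 0.01).
#' @return A tibble with columns `sample_id`, `reason`
#'   (`"low_top_taxon"` or `"all_zero"`).
#' @export
flag_suspect_samples <- function(counts, frac = 0.01) {
  validate_count_table(counts)
  stopifnot(frac > 0, frac < 1)
  m <- count_matrix(counts)
  row_max <- apply(m, 1, max)
  flags <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (all(col == 0)) {
      return(tibble::tibble(sample_id = colnames(m)[j], reason = "all_zero"))
    }
    top <- which.max(col)
    if (col[top] < frac * row_max[top]) {
      return(tibble::tibble(sample_id = colnames(m)[j],
                            reason = "low_top_taxon"))
    }
    tibble::tibble(sample_id = character(0), reason = character(0))
  })
  flags
}

#' Add ancestor clade rows by summing descendant counts
#'
#' Every proper ancestor of any lineage in the table is added as a row
#' whose per-sample value is the sum over all terminal rows descending from
#' it. Existing rows are left untouched; ancestors already present are not
#' duplicated.
#'
#' @param counts A count tibble of terminal phylotypes.
#' @return The count tibble with ancestor rows appended (ordered by
#'   lineage depth then name).
#' @export
aggregate_clades <- function(counts) {
  validate_count_table(counts)
  m <- count_matrix(counts)
  anc <- setdiff(
    unique(unlist(lapply(counts$lineage, lineage_ancestors))),
    counts$lineage
  )
  if (length(anc) == 0) return(counts)
  anc_rows <- t(vapply(anc, function(a) {
    desc <- startsWith(counts$lineage, paste0(a, "|"))
    colSums(m[desc, , drop = FALSE])
  }, numeric(ncol(m))))
  out <- dplyr::bind_rows(
    counts,
    tibble::as_tibble(cbind(tibble::tibble(lineage = anc),
                            as.data.frame(anc_rows, check.names = FALSE)))
  )
  out[order(lineage_depth(out$lineage), out$lineage), , drop = FALSE]
}

# terminal rows = rows with no descendant row present in the table
is_terminal_row <- function(lineage) {
  vapply(lineage, function(a) !any(startsWith(lineage, paste0(a, "|"))),
         logical(1))
}

#' Convert counts to relative abundances
#'
#' Each sample is divided by its total over terminal phylotype rows, so the
#' terminal rows of every sample sum to one. Ancestor rows (if present)
#' are divided by the same totals, which keeps them equal to the sum of
#' their normalized descendants — normalizing before or after
#' [aggregate_clades()] gives the same result.
#'
#' @param counts A count tibble (leaves only, or with ancestor rows).
#' @return The tibble with values rescaled to relative abundances.
#' @export
to_relative <- function(counts) {
  validate_count_table(counts)
  m <- count_matrix(counts)
  leaf <- is_terminal_row(counts$lineage)
  tot <- colSums(m[leaf, , drop = FALSE])
  if (any(tot == 0)) {
    stop("zero-sum sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  }
  counts[, -1] <- as.data.frame(sweep(m, 2, tot, "/"), check.names = FALSE)
  counts
}

#' Build the composite feature-by-subject-visit matrix
#'
#' Stacks per-body-site relative abundance rows into one matrix whose rows
#' are `(lineage, body site)` features and whose columns are subject-visit
#' points; a subject sampled at two visits contributes two columns. Body
#' sites missing for a subject-visit yield `NA` entries. Rows whose
#' fraction of zero (or missing) entries strictly exceeds
#' `zero_frac_cutoff` are removed.
#'
#' @param rel A relative abundance tibble covering all samples
#'   (`lineage` + sample columns), e.g. from [to_relative()].
#' @param metadata Sample metadata tibble with `sample_id`, `subject`,
#'   `visit`, `body_site`.
#' @param zero_frac_cutoff Strict upper bound on the zero fraction of a
#'   retained row (default 2/3).
#' @return A tibble with columns `feature` (`"lineage@body_site"`),
#'   `lineage`, `body_site`, and one numeric column per subject-visit id
#'   (`"subject:visit"`).
#' @export
build_composite <- function(rel, metadata, zero_frac_cutoff = 2 / 3) {
  validate_count_table(rel)
  stopifnot(zero_frac_cutoff > 0, zero_frac_cutoff <= 1)
  md <- metadata[metadata$sample_id %in% names(rel)[-1], , drop = FALSE]
  if (nrow(md) == 0) stop("no metadata rows match sample columns", call. = FALSE)
  md$sv <- paste(md$subject, md$visit, sep = ":")
  sites <- sort(unique(md$body_site))
  svs <- sort(unique(md$sv))
  if (length(sites) > 1) {
    per_site <- split(md$sv, md$body_site)
    if (length(Reduce(intersect, per_site)) == 0) {
      stop("no overlapping subject-visit columns across body sites",
           call. = FALSE)
    }
  }
  m <- count_matrix(rel)
  blocks <- purrr::map(sites, function(s) {
    ms <- md[md$body_site == s, , drop = FALSE]
    # one sample per (subject, visit, site) expected; first wins otherwise
    ms <- ms[!duplicated(ms$sv), , drop = FALSE]
    block <- matrix(NA_real_, nrow = nrow(m), ncol = length(svs),
                    dimnames = list(NULL, svs))
    block[, ms$sv] <- m[, ms$sample_id, drop = FALSE]
    tibble::as_tibble(cbind(
      tibble::tibble(
        feature = paste0(rel$lineage, "@", s),
        lineage = rel$lineage,
        body_site = s
      ),
      as.data.frame(block, check.names = FALSE)
    ))
  })
  out <- dplyr::bind_rows(blocks)
  vals <- as.matrix(out[, svs, drop = FALSE])
  zero_frac <- rowMeans(is.na(vals) | vals == 0)
  out[zero_frac <= zero_frac_cutoff, , drop = FALSE]
}

#' Numeric matrix view of a composite table
#' @param composite A composite tibble from [build_composite()].
#' @return Numeric matrix, rows named by feature id.
#' @export
composite_matrix <- function(composite) {
  meta <- intersect(c("feature", "lineage", "body_site"), names(composite))
  m <- as.matrix(composite[, setdiff(names(composite), meta), drop = FALSE])
  rownames(m) <- composite$feature
  m
}

composite_meta <- function(composite) {
  composite[, c("feature", "lineage", "body_site"), drop = FALSE]
}

#' Write / read a composite matrix as TSV
#' @param composite A composite tibble.
#' @param path Output path.
#' @return `path`, invisibly (writer); a composite tibble (reader).
#' @export
write_composite <- function(composite, path) {
  utils::write.table(
    composite[, setdiff(names(composite), c("lineage", "body_site"))],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_composite
#' @export
read_composite <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  parts <- strsplit(df$feature, "@", fixed = TRUE)
  tibble::as_tibble(cbind(
    tibble::tibble(
      feature = df$feature,
      lineage = vapply(parts, `[`, character(1), 1),
      body_site = vapply(parts, `[`, character(1), 2)
    ),
    df[, -1, drop = FALSE]
  ))
}
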