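#' Parse a pipe-delimited taxonomic lineage
#'
#' Lineages name a clade by its full taxonomic path from the domain down,
#' e.g. `"Bacteria|Firmicutes|Bacilli"`. The prefix relation between two
#' parsed lineages defines ancestry: `"Bacteria|Firmicutes"` is an ancestor
#' of every clade whose path starts with those two levels.
#'
#' @param text Character vector of pipe-delimited lineage strings.
#' @return A list of character vectors (one per input string), each the
#'   ordered clade names from domain to terminal clade.
#' @examples
#' parse_lineage("Bacteria|Firmicutes|Bacilli")
#' @export
parse_lineage <- function(text) {
  if (!is.character(text) || length(text) == 0) {
    stop("`text` must be a non-empty character vector", call. = FALSE)
  }
  out <- strsplit(text, "|", fixed = TRUE)
  bad <- vapply(
    seq_along(out),
    function(i) {
      lv <- out[[i]]
      is.na(text[[i]]) || !nzchar(text[[i]]) || length(lv) == 0 ||
        any(!nzchar(lv)) || endsWith(text[[i]], "|")
    },
    logical(1)
  )
  if (any(bad)) {
    stop(
      "malformed lineage (empty string or empty level): ",
      paste(utils::head(text[bad], 3), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Test strict taxonomic ancestry between two lineages
#'
#' @param a,b Pipe-delimited lineage strings or parsed level vectors.
#' @return `TRUE` iff the levels of `a` are a strict prefix of the levels of
#'   `b` (a clade is not its own ancestor).
#' @examples
#' is_ancestor("Bacteria|Firmicutes", "Bacteria|Firmicutes|Bacilli")
#' @export
is_ancestor <- function(a, b) {
  la <- if (is.character(a) && length(a) == 1) parse_lineage(a)[[1]] else a
  lb <- if (is.character(b) && length(b) == 1) parse_lineage(b)[[1]] else b
  length(la) < length(lb) && identical(la, lb[seq_along(la)])
}

#' @rdname is_ancestor
#' @details `lineage_related()` is `TRUE` when either lineage is a strict
#'   ancestor of the other or the two are identical; this is the
#'   parent/descendant exclusion used when scoring clade pairs within one
#'   body site.
#' @export
lineage_related <- function(a, b) {
  identical(a, b) || is_ancestor(a, b) || is_ancestor(b, a)
}

#' Enumerate proper ancestors of a lineage
#'
#' @param lineage A pipe-delimited lineage string.
#' @return Character vector of ancestor lineage strings, outermost first;
#'   empty for a depth-1 lineage.
#' @export
lineage_ancestors <- function(lineage) {
  lv <- parse_lineage(lineage)[[1]]
  if (length(lv) <= 1) return(character(0))
  vapply(
    seq_len(length(lv) - 1),
    function(k) paste(lv[seq_len(k)], collapse = "|"),
    character(1)
  )
}

#' Depth (number of levels) of lineage strings
#' @param text Character vector of lineage strings.
#' @return Integer vector of level counts.
#' @export
lineage_depth <- function(text) {
  lengths(parse_lineage(text))
}

# Vectorized strict-prefix test on two equal-length character vectors of
# lineage strings; used for pair filtering without re-parsing in loops.
lineage_related_chr <- function(a, b) {
  same <- a == b
  pref_ab <- startsWith(b, paste0(a, "|"))
  pref_ba <- startsWith(a, paste0(b, "|"))
  same | pref_ab | pref_ba
}
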