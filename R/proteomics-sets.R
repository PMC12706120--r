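#' Exclusive (upset-style) and pairwise set intersections
#'
#' For every non-empty combination of the input sets, counts the elements
#' belonging to *exactly* that combination (the bar heights of an upset
#' plot), plus the simple pairwise intersection sizes.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return A `set_overlap` list of tibbles: `exclusive` (`combination`,
#'   `degree`, `count`) sorted by degree then count, and `pairwise`
#'   (`set1`, `set2`, `count`).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  counts <- table(pattern[nzchar(pattern)])
  exclusive <- tibble::tibble(
    combination = names(counts),
    degree = lengths(strsplit(names(counts), "&", fixed = TRUE)),
    count = as.integer(counts)
  ) |> dplyr::arrange(.data$degree, dplyr::desc(.data$count))
  pairs <- utils::combn(names(sets), 2)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(k) {
    tibble::tibble(set1 = pairs[1, k], set2 = pairs[2, k],
                   count = length(intersect(sets[[pairs[1, k]]],
                                            sets[[pairs[2, k]]])))
  }) |> dplyr::bind_rows()
  structure(list(exclusive = exclusive, pairwise = pairwise,
                 set_sizes = lengths(sets)),
            class = "set_overlap")
}

#' @export
print.set_overlap <- function(x, ...) {
  cat("<set_overlap> exclusive intersections:\n")
  print(x$exclusive, n = 20)
  invisible(x)
}

#' Proteins altered in both cohorts
#'
#' The "shared between disease stages" logic: an element counts as shared
#' when it is differentially expressed (up or down) in cohort A *and* in
#' cohort B, i.e. `(up_a | down_a) & (up_b | down_b)`.
#'
#' @param up_a,down_a,up_b,down_b Character vectors of protein ids.
#' @return Character vector of shared proteins.
#' @export
shared_de_proteins <- function(up_a, down_a, up_b, down_b) {
  intersect(union(up_a, down_a), union(up_b, down_b))
}

#' Named gene-set collection with a universe
#'
#' @param sets Named list of character vectors; identifiers are harmonised
#'   case-insensitively (upper-cased).
#' @param universe Character vector of all assayable identifiers; sets are
#'   intersected with it.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            !anyDuplicated(names(sets)), length(universe) >= 1)
  universe <- unique(toupper(universe))
  sets <- lapply(sets, function(s) intersect(unique(toupper(s)), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Second-column description written per set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(n) {
    paste(c(n, description, sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Cross-reference DE protein sets with a curated list
#'
#' Case-insensitive identifier match of the up/down-regulated proteins
#' against a curated pathway list (e.g. autophagy and endo-lysosomal
#' pathway proteins).
#'
#' @param up,down Character vectors of DE protein ids.
#' @param curated Character vector of curated identifiers (non-empty).
#' @return A list: `table` (tibble `protein`, `direction`, `in_curated`) and
#'   `summary` (tibble `n_altered_in_curated`, `n_up_in_curated`,
#'   `n_down_in_curated`, `n_curated`).
#' @export
crossref_curated <- function(up, down, curated) {
  if (length(curated) == 0) abort("curated list is empty")
  cur <- unique(toupper(curated))
  tab <- tibble::tibble(
    protein = c(up, down),
    direction = c(rep("up", length(up)), rep("down", length(down)))
  )
  tab$in_curated <- toupper(tab$protein) %in% cur
  list(
    table = tab,
    summary = tibble::tibble(
      n_altered_in_curated = sum(tab$in_curated),
      n_up_in_curated = sum(tab$in_curated & tab$direction == "up"),
      n_down_in_curated = sum(tab$in_curated & tab$direction == "down"),
      n_curated = length(cur)
    )
  )
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided enrichment p value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution with universe size `N`,
#' set size `K`, selection size `n` and overlap `k`; p values are
#' BH-adjusted across sets. The odds ratio is computed from the 2x2
#' membership table.
#'
#' @param selected Character vector of selected (e.g. DE) identifiers.
#' @param collection A [gene_set_collection()] (or named list of sets, in
#'   which case `universe` must be given).
#' @param universe Universe identifiers, required if `collection` is a list.
#' @return Tibble: `set`, `set_size`, `overlap`, `expected`, `odds_ratio`,
#'   `p_value`, `adj_p_value`.
#' @export
ora_hypergeometric <- function(selected, collection, universe = NULL) {
  if (!inherits(collection, "gene_set_collection")) {
    if (is.null(universe)) abort("`universe` required for a bare set list")
    collection <- gene_set_collection(collection, universe)
  }
  uni <- collection$universe
  if (length(uni) == 0) abort("empty universe")
  sel <- intersect(unique(toupper(selected)), uni)
  N <- length(uni); n <- length(sel)
  out <- purrr::imap(collection$sets, function(s, nm) {
    K <- length(s)
    k <- length(intersect(sel, s))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max(1e-12, (n - k) * (K - k))
    tibble::tibble(set = nm, set_size = K, overlap = k,
                   expected = n * K / N, odds_ratio = or, p_value = p)
  }) |> dplyr::bind_rows()
  out$adj_p_value <- bh_adjust(out$p_value)
  out
}
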