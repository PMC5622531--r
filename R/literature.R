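# Literature side: MeSH descriptors, co-occurrence counts, subtree
# restriction and top-K comorbidity ranking.

#' Read a MeSH descriptor table
#'
#' Parses a delimited text file of MeSH descriptors with columns `dui`
#' (descriptor unique identifier, `D` followed by digits), `name` (preferred
#' term) and `tree_numbers` (semicolon-separated dot addresses in the MeSH
#' hierarchy, e.g. `"C20.111.199"`). Pipe or tab delimiter is auto-detected
#' from the header row; a header is required.
#'
#' @param file Path to the descriptor file (UTF-8).
#' @return A tibble with columns `dui`, `name` and list-column
#'   `tree_numbers`.
#' @export
#' @examples
#' f <- system.file("extdata", "mesh_descriptors.tsv", package = "litcomorbid")
#' read_mesh_descriptors(f)
read_mesh_descriptors <- function(file) {
  header <- readLines(file, n = 1L, encoding = "UTF-8")
  delim <- if (grepl("|", header, fixed = TRUE)) "|" else "\t"
  raw <- readr::read_delim(file, delim = delim, trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  parse_mesh_descriptors(raw)
}

#' Validate a descriptor table
#'
#' @param df Data frame with character columns `dui`, `name`, `tree_numbers`
#'   (semicolon-joined) or an already-split list-column.
#' @return A validated tibble; duplicate DUIs or malformed identifiers and
#'   tree numbers are rejected with an error naming the offending row.
#' @export
parse_mesh_descriptors <- function(df) {
  check_columns(df, c("dui", "name", "tree_numbers"), "descriptor table")
  out <- as_tibble(df[c("dui", "name", "tree_numbers")])
  if (!is.list(out$tree_numbers)) {
    out$tree_numbers <- stringr::str_split(out$tree_numbers %||% "", ";")
  }
  out$tree_numbers <- purrr::map(out$tree_numbers,
                                 function(t) stringr::str_trim(t[nzchar(stringr::str_trim(t))]))
  bad_dui <- which(!is_dui(out$dui))
  if (length(bad_dui) > 0) {
    stop_field("malformed descriptor identifier '%s' at row %d",
               out$dui[bad_dui[1]], bad_dui[1], class = "litcomorbid_parse_error")
  }
  dup <- out$dui[duplicated(out$dui)]
  if (length(dup) > 0) {
    stop_field("duplicate descriptor identifier(s): %s",
               paste(unique(dup), collapse = ", "),
               class = "litcomorbid_parse_error")
  }
  bad_tree <- purrr::map_lgl(out$tree_numbers, function(t) any(!is_tree_number(t)))
  if (any(bad_tree)) {
    i <- which(bad_tree)[1]
    stop_field("malformed tree number for descriptor %s at row %d",
               out$dui[i], i, class = "litcomorbid_parse_error")
  }
  out
}

#' Read a descriptor co-occurrence file
#'
#' Parses a delimited file of pairwise MEDLINE citation co-occurrence counts,
#' columns `dui_a`, `dui_b`, `count` (an optional `year` column is accepted
#' and ignored). Pairs are canonicalised as unordered (`dui_a < dui_b`
#' lexicographically); duplicate pair rows are summed with a warning.
#'
#' @param file Path to the co-occurrence file (UTF-8, pipe or tab delimited).
#' @return A tibble with columns `dui_a`, `dui_b`, `count`.
#' @export
read_cooccurrence <- function(file) {
  header <- readLines(file, n = 1L, encoding = "UTF-8")
  delim <- if (grepl("|", header, fixed = TRUE)) "|" else "\t"
  raw <- readr::read_delim(file, delim = delim, trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  parse_cooccurrence(raw)
}

#' Validate and canonicalise co-occurrence records
#'
#' @param df Data frame with columns `dui_a`, `dui_b`, `count`.
#' @return Tibble of unordered pairs with non-negative integer counts.
#' @export
parse_cooccurrence <- function(df) {
  check_columns(df, c("dui_a", "dui_b", "count"), "co-occurrence table")
  out <- as_tibble(df[c("dui_a", "dui_b", "count")])
  out$count <- as.integer(out$count)
  bad <- which(!is_dui(out$dui_a) | !is_dui(out$dui_b) |
                 is.na(out$count) | out$count < 0)
  if (length(bad) > 0) {
    stop_field("invalid co-occurrence record at row %d (%s, %s, %s)",
               bad[1], df$dui_a[bad[1]], df$dui_b[bad[1]], df$count[bad[1]],
               class = "litcomorbid_parse_error")
  }
  self <- out$dui_a == out$dui_b
  if (any(self)) {
    stop_field("self-pair at row %d (%s)", which(self)[1], out$dui_a[which(self)[1]],
               class = "litcomorbid_parse_error")
  }
  swap <- out$dui_a > out$dui_b
  tmp <- out$dui_a[swap]
  out$dui_a[swap] <- out$dui_b[swap]
  out$dui_b[swap] <- tmp
  if (anyDuplicated(out[c("dui_a", "dui_b")]) > 0) {
    warn("duplicate co-occurrence pairs found; counts summed")
    out <- out |>
      group_by(.data$dui_a, .data$dui_b) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
  out
}

#' Descriptors under a MeSH subtree
#'
#' Returns the descriptor identifiers having at least one tree number equal
#' to `root_prefix` or lying below it. Matching respects dot boundaries: a
#' prefix `"C20.111"` matches `"C20.111"` and `"C20.111.199"` but never
#' `"C20.1119"` — tree numbers are positional addresses, not strings.
#'
#' @param descriptors Descriptor tibble from [read_mesh_descriptors()].
#' @param root_prefix A tree-number prefix, e.g. `"C20.111"` (the autoimmune
#'   diseases subtree).
#' @return Character vector of matching DUIs.
#' @export
mesh_subtree <- function(descriptors, root_prefix) {
  if (!is_tree_number(root_prefix)) {
    stop_field("'%s' is not a valid tree-number prefix", root_prefix)
  }
  hit <- purrr::map_lgl(descriptors$tree_numbers, function(t) {
    any(t == root_prefix | startsWith(t, paste0(root_prefix, ".")))
  })
  descriptors$dui[hit]
}

#' Rank the top-K comorbidities of an index disease
#'
#' Restricts co-occurrence records to partners of `index_dui` that belong to
#' `allowed` (typically a MeSH subtree, see [mesh_subtree()]), and returns the
#' `k` partners with the highest citation counts, sorted by count descending
#' (ties broken by DUI for display). If several partners are tied exactly at
#' the rank-`k` cut, all tied members are kept — with a warning — rather than
#' truncated arbitrarily, so the panel may exceed `k`.
#'
#' @param records Co-occurrence tibble from [read_cooccurrence()].
#' @param index_dui Descriptor identifier of the index disease.
#' @param allowed Character vector of eligible partner DUIs; the index
#'   disease itself is always excluded.
#' @param k Requested panel size (positive integer).
#' @return A `comorbidity_panel`: a tibble with columns `rank`, `dui`,
#'   `count`, carrying the index DUI and `k` as attributes.
#' @export
rank_comorbidities <- function(records, index_dui, allowed, k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  k <- as.integer(k)
  allowed <- setdiff(allowed, index_dui)
  partners <- records |>
    filter(.data$dui_a == index_dui | .data$dui_b == index_dui) |>
    mutate(dui = ifelse(.data$dui_a == index_dui, .data$dui_b, .data$dui_a)) |>
    filter(.data$dui %in% allowed) |>
    select("dui", "count") |>
    arrange(desc(.data$count), .data$dui)
  if (nrow(partners) > k) {
    cut_count <- partners$count[k]
    keep <- partners$count > cut_count
    tied <- partners$count == cut_count
    if (sum(tied) > k - sum(keep)) {
      warn(sprintf("tie at rank %d (count %d): keeping %d members instead of %d",
                   k, cut_count, sum(keep) + sum(tied), k))
    }
    partners <- partners[keep | tied, ]
  }
  out <- mutate(partners, rank = row_number(), .before = 1)
  structure(out,
            class = c("comorbidity_panel", class(tibble())),
            index_dui = index_dui, k = k)
}

#' @export
print.comorbidity_panel <- function(x, ...) {
  cat(sprintf("<comorbidity panel> index %s, top %d requested, %d members\n",
              attr(x, "index_dui"), attr(x, "k"), nrow(x)))
  NextMethod()
}

#' @rdname rank_comorbidities
#' @param x A `comorbidity_panel`.
#' @param ... Unused.
#' @method tidy comorbidity_panel
#' @export
tidy.comorbidity_panel <- function(x, ...) {
  as_tibble(x)
}

#' @rdname rank_comorbidities
#' @method glance comorbidity_panel
#' @export
glance.comorbidity_panel <- function(x, ...) {
  tibble(index_dui = attr(x, "index_dui"), k = attr(x, "k"),
         n_members = nrow(x),
         top_count = if (nrow(x) > 0) x$count[1] else NA_integer_)
}
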