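#' Construct a same-list set
#'
#' In a *same* set the presentation order never changes: every list in the set
#' is the base list. Same sets can be learned with purely positional
#' (item-independent) cues because every item keeps its serial position on
#' every repetition.
#'
#' @param items Character vector of six unique single-character symbols (base
#'   list, in presentation order). Constructors accept other even lengths
#'   where the design generalises, but the analysis pipeline is specified for
#'   six-item lists.
#' @param n_lists Number of (identical) lists in the set.
#' @param set_id Label for the set.
#'
#' @return A `list_set` object: a list with fields `set_id`, `list_type`,
#'   `base_items`, and `lists` (a list of character vectors, each a
#'   permutation of `base_items`).
#' @seealso [make_spun_set()], [make_scrambled_set()], [check_balance()]
#' @export
#' @examples
#' make_same_set(LETTERS[1:6], n_lists = 6)
make_same_set <- function(items, n_lists, set_id = "same1") {
  items <- validate_items(items)
  if (!is.numeric(n_lists) || length(n_lists) != 1L || n_lists < 1) {
    stop("`n_lists` must be a positive count.", call. = FALSE)
  }
  new_list_set(set_id, "same", items, rep(list(items), as.integer(n_lists)))
}

#' Construct a spun-list set
#'
#' A *spun* set contains the six right-rotations of the base list: list k is
#' the base list rotated right by k - 1 (the last item moves to the front at
#' each step), e.g. ABCDEF, FABCDE, EFABCD, ... Each item therefore appears
#' once in every serial position (position-balanced) while keeping the same
#' neighbours throughout, so spun sets can be learned with item-dependent
#' (chaining) cues but not with fixed positional cues.
#'
#' @inheritParams make_same_set
#' @return A `list_set` with one list per rotation (`n` lists for `n` items).
#' @export
#' @examples
#' make_spun_set(LETTERS[1:6])
make_spun_set <- function(items, set_id = "spun1") {
  items <- validate_items(items)
  n <- length(items)
  lists <- lapply(seq_len(n) - 1L, function(k) {
    if (k == 0L) items else c(items[(n - k + 1L):n], items[1:(n - k)])
  })
  new_list_set(set_id, "spun", items, lists)
}

#' Construct a scrambled-list set (Williams balanced Latin square)
#'
#' A *scrambled* set reorders the base items so that, across the set, each
#' item appears exactly once in each serial position and each ordered pair of
#' distinct items is adjacent exactly once. Scrambled sets therefore provide
#' neither consistent positions nor consistent neighbours. The construction
#' is the Williams design for even n: the first row visits columns
#' 1, 2, n, 3, n - 1, 4, ... and each subsequent row increments every entry
#' by one (mod n).
#'
#' @inheritParams make_same_set
#' @return A `list_set` whose six lists form a balanced Latin square over
#'   `items`; [check_balance()] returns both flags `TRUE`.
#' @export
#' @examples
#' sq <- make_scrambled_set(c("M", "N", "O", "P", "Q", "R"))
#' check_balance(sq)
make_scrambled_set <- function(items, set_id = "scrambled1") {
  items <- validate_items(items)
  n <- length(items)
  if (n %% 2L != 0L) {
    stop("The Williams construction used here requires an even number of items.",
         call. = FALSE)
  }
  first <- integer(n)
  first[1L] <- 1L
  lo <- 2L
  hi <- n
  for (j in 2:n) {
    if (j %% 2L == 0L) {
      first[j] <- lo
      lo <- lo + 1L
    } else {
      first[j] <- hi
      hi <- hi - 1L
    }
  }
  lists <- lapply(seq_len(n) - 1L, function(k) items[((first - 1L + k) %% n) + 1L])
  new_list_set(set_id, "scrambled", items, lists)
}

#' Check position and adjacency balance of a list set
#'
#' Counts, exhaustively, how often each item occupies each serial position and
#' how often each ordered pair of distinct items occurs in adjacent positions
#' across the set. The set is *position-balanced* when every item appears
#' exactly once in every position, and *adjacency-balanced* when every
#' ordered pair of distinct items is adjacent exactly once (the defining
#' properties of a balanced Latin square).
#'
#' @param set A `list_set` (or a bare list of equal-length character vectors,
#'   each a permutation of the first).
#' @return A list with logical fields `position_balanced` and
#'   `adjacency_balanced`, plus the underlying count tables
#'   `position_counts` (item x position) and `adjacency_counts`
#'   (predecessor x successor).
#' @export
#' @examples
#' check_balance(make_spun_set(LETTERS[1:6]))  # position yes, adjacency no
check_balance <- function(set) {
  if (inherits(set, "list_set")) {
    lists <- set$lists
    items <- set$base_items
  } else if (is.list(set)) {
    lists <- set
    items <- sort(unique(unlist(set)))
  } else {
    stop("`set` must be a list_set or a list of lists.", call. = FALSE)
  }
  n <- length(items)
  for (l in lists) {
    if (anyDuplicated(l) || length(l) != n || !setequal(l, items)) {
      stop("Malformed list set: every list must be a permutation of the base items.",
           call. = FALSE)
    }
  }
  pos <- matrix(0L, n, n, dimnames = list(item = items, position = seq_len(n)))
  adj <- matrix(0L, n, n, dimnames = list(prev = items, next_ = items))
  for (l in lists) {
    idx <- match(l, items)
    pos[cbind(idx, seq_len(n))] <- pos[cbind(idx, seq_len(n))] + 1L
    adj[cbind(idx[-n], idx[-1L])] <- adj[cbind(idx[-n], idx[-1L])] + 1L
  }
  off_diag <- adj[row(adj) != col(adj)]
  list(
    position_balanced = all(pos == 1L),
    adjacency_balanced = all(off_diag == 1L) && all(diag(adj) == 0L),
    position_counts = pos,
    adjacency_counts = adj
  )
}

#' @export
print.list_set <- function(x, ...) {
  cat(sprintf("<list_set '%s': %s, %d lists of %d items>\n",
              x$set_id, x$list_type, length(x$lists), length(x$base_items)))
  for (i in seq_along(x$lists)) {
    cat(sprintf("  list %d: %s\n", i, paste(x$lists[[i]], collapse = "")))
  }
  invisible(x)
}

#' Tabulate a list set in long form
#'
#' @param x A `list_set`.
#' @param ... Unused.
#' @return A tibble with columns `set_id`, `list_type`, `list_index`,
#'   `position`, `symbol` -- the CSV serialisation dialect used by
#'   [write_list_set()].
#' @export
as_tibble.list_set <- function(x, ...) {
  n <- length(x$base_items)
  tibble::tibble(
    set_id = x$set_id,
    list_type = x$list_type,
    list_index = rep(seq_along(x$lists), each = n),
    position = rep(seq_len(n), times = length(x$lists)),
    symbol = unlist(x$lists)
  )
}

#' Write / read a list set as CSV
#'
#' Serialises the long form produced by [as_tibble.list_set()].
#'
#' @param set A `list_set`.
#' @param path File path.
#' @return `write_list_set()` returns `set` invisibly; `read_list_set()`
#'   returns a `list_set`.
#' @export
write_list_set <- function(set, path) {
  readr::write_csv(as_tibble.list_set(set), path)
  invisible(set)
}

#' @rdname write_list_set
#' @export
read_list_set <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    set_id = readr::col_character(),
    list_type = readr::col_character(),
    list_index = readr::col_integer(),
    position = readr::col_integer(),
    symbol = readr::col_character()
  ))
  df <- dplyr::arrange(df, .data$list_index, .data$position)
  lists <- unname(split(df$symbol, df$list_index))
  new_list_set(df$set_id[1L], df$list_type[1L], lists[[1L]], lists)
}

# -- internal ---------------------------------------------------------------

validate_items <- function(items) {
  items <- as.character(items)
  if (anyDuplicated(items)) {
    stop("`items` must be distinct symbols.", call. = FALSE)
  }
  if (length(items) < 2L) {
    stop("`items` must contain at least two symbols.", call. = FALSE)
  }
  if (any(is.na(items)) || any(nchar(items) != 1L)) {
    stop("`items` must be single, non-missing characters.", call. = FALSE)
  }
  items
}

new_list_set <- function(set_id, list_type, base_items, lists) {
  structure(
    list(set_id = as.character(set_id), list_type = list_type,
         base_items = base_items, lists = lists),
    class = "list_set"
  )
}
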