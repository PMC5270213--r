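#' Parse Enzyme Commission (EC) numbers
#'
#' An EC number is a four-level dotted identifier, `class.subclass.subdivision.
#' serial`, e.g. `5.4.4.2` (isochorismate synthase). Trailing positions may be
#' the wildcard `-` (e.g. `1.-.-.-`), meaning the annotation is only resolved
#' down to some level; a wildcard may never sit left of a concrete digit.
#' The class digit identifies one of the six top-level reaction types
#' (1 oxidoreductases, 2 transferases, 3 hydrolases, 4 lyases, 5 isomerases,
#' 6 ligases).
#'
#' @param x character vector of EC strings, four dot-separated fields,
#'   wildcard `-`.
#' @param max_class largest admissible class digit. Default 6, the classical
#'   six-class universe; set 7 to admit modern translocases.
#' @param allow_preliminary if `TRUE`, preliminary serial numbers of the form
#'   `n12` have their `n` prefix stripped; by default such forms are rejected
#'   so that provisional annotations cannot silently enter the statistics.
#'
#' @return A tibble with one row per input: `ec` (canonical rendering) and the
#'   integer columns `class`, `subclass`, `subdivision`, `serial` (`NA` marks
#'   a wildcard position).
#'
#' @examples
#' parse_ec(c("5.4.4.2", "1.-.-.-"))
#' @export
parse_ec <- function(x, max_class = 6, allow_preliminary = FALSE) {
  if (length(x) == 0) {
    return(tibble::tibble(
      ec = character(), class = integer(), subclass = integer(),
      subdivision = integer(), serial = integer()
    ))
  }
  x_chr <- as.character(x)
  if (anyNA(x_chr) || any(!nzchar(trimws(x_chr)))) {
    stop("EC strings must be non-empty and non-missing", call. = FALSE)
  }
  x_chr <- trimws(x_chr)
  parts <- strsplit(x_chr, ".", fixed = TRUE)
  bad_len <- lengths(parts) != 4L
  if (any(bad_len)) {
    stop(
      "malformed EC number (need four dot-separated fields): ",
      paste(unique(x_chr[bad_len]), collapse = ", "),
      call. = FALSE
    )
  }
  mat <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  if (allow_preliminary) {
    mat[, 4] <- sub("^n(?=[0-9]+$)", "", mat[, 4], perl = TRUE)
  }
  field_ok <- grepl("^([0-9]+|-)$", mat)
  if (!all(field_ok)) {
    bad <- unique(x_chr[rowSums(matrix(!field_ok, ncol = 4L)) > 0])
    stop("malformed EC field in: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  digits <- matrix(suppressWarnings(as.integer(mat)), ncol = 4L)

  # wildcards must be a contiguous right suffix
  wc <- is.na(digits)
  bad_wc <- (wc[, 1] & !(wc[, 2] & wc[, 3] & wc[, 4])) |
    (wc[, 2] & !(wc[, 3] & wc[, 4])) |
    (wc[, 3] & !wc[, 4]) |
    wc[, 1]
  # a fully wildcarded class position is never meaningful
  if (any(bad_wc)) {
    stop(
      "wildcard left of a concrete digit (or wildcard class) in: ",
      paste(unique(x_chr[bad_wc]), collapse = ", "),
      call. = FALSE
    )
  }
  concrete_bad <- !wc & digits < 1L
  if (any(concrete_bad)) {
    stop(
      "EC fields must be positive integers: ",
      paste(unique(x_chr[rowSums(concrete_bad) > 0]), collapse = ", "),
      call. = FALSE
    )
  }
  out_of_range <- digits[, 1] > max_class
  if (any(out_of_range)) {
    stop(
      "EC class digit outside 1..", max_class, ": ",
      paste(unique(x_chr[out_of_range]), collapse = ", "),
      call. = FALSE
    )
  }
  canon <- apply(digits, 1L, function(d) {
    paste(ifelse(is.na(d), "-", as.character(d)), collapse = ".")
  })
  tibble::tibble(
    ec = canon,
    class = digits[, 1],
    subclass = digits[, 2],
    subdivision = digits[, 3],
    serial = digits[, 4]
  )
}

#' @rdname parse_ec
#' @return `ec_canonical()` returns the canonical character rendering.
#' @export
ec_canonical <- function(x, max_class = 6, allow_preliminary = FALSE) {
  parse_ec(x, max_class = max_class, allow_preliminary = allow_preliminary)$ec
}

#' EC hierarchy levels
#'
#' The four grouping depths used throughout the package: `"class"` (first
#' digit), `"subclass"` (two digits), `"subdivision"` (three digits — enzymes
#' sharing it share reaction chemistry), `"full"` (all four digits).
#'
#' @return character vector of level names, shallow to deep.
#' @export
ec_levels <- function() c("class", "subclass", "subdivision", "full")

ec_level_depth <- function(level) {
  level <- match.arg(level, ec_levels())
  match(level, ec_levels())
}

#' Grouping key of an EC number at a hierarchy level
#'
#' Truncates EC numbers to the dotted prefix of the requested depth, e.g.
#' `5.4.4.2` at level `"subdivision"` gives `"5.4.4"`. Records whose
#' annotation is wildcarded above the requested depth are *incomplete at
#' level*: they yield `NA` (the statistics drop them from that level's
#' denominator) or an error under `strict = TRUE`.
#'
#' @param x character vector of EC strings.
#' @param level one of [ec_levels()].
#' @param strict error (instead of `NA`) on ECs incomplete at `level`.
#' @inheritParams parse_ec
#' @return character vector of grouping keys; `NA` where incomplete.
#' @examples
#' ec_key("5.4.4.2", "subdivision")
#' ec_key("2.6.1.85", "class")
#' @export
ec_key <- function(x, level = "full", strict = FALSE, max_class = 6,
                   allow_preliminary = FALSE) {
  depth <- ec_level_depth(level)
  if (length(x) == 0) {
    return(character())
  }
  p <- parse_ec(x, max_class = max_class, allow_preliminary = allow_preliminary)
  digit_cols <- c("class", "subclass", "subdivision", "serial")
  digits <- as.matrix(p[digit_cols[seq_len(depth)]])
  incomplete <- rowSums(is.na(digits)) > 0
  if (strict && any(incomplete)) {
    stop(
      "EC number incomplete at level '", level, "': ",
      paste(unique(p$ec[incomplete]), collapse = ", "),
      call. = FALSE
    )
  }
  key <- apply(digits, 1L, paste, collapse = ".")
  key[incomplete] <- NA_character_
  key
}

#' Is an EC number fully specified down to a level?
#'
#' @inheritParams ec_key
#' @return logical vector.
#' @export
ec_complete_at <- function(x, level = "full", max_class = 6,
                           allow_preliminary = FALSE) {
  !is.na(ec_key(x, level,
    strict = FALSE, max_class = max_class,
    allow_preliminary = allow_preliminary
  ))
}

#' Do two EC numbers agree at a hierarchy level?
#'
#' @param a,b character vectors of EC strings (recycled to common length).
#' @inheritParams ec_key
#' @return logical vector; `TRUE` iff the grouping keys at `level` are equal.
#'   With `strict = FALSE`, comparisons involving an EC incomplete at `level`
#'   give `NA`.
#' @export
same_at_level <- function(a, b, level = "full", strict = TRUE) {
  ka <- ec_key(a, level, strict = strict)
  kb <- ec_key(b, level, strict = strict)
  ka == kb
}
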