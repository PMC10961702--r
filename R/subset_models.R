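# Subset-model nomenclature and set algebra. A subset model is named
# "A" followed by 14 binary characters; character i corresponds to assay Ai
# (the leftmost character after "A" is A1), and a '1' marks assay membership.
# For example "A10000000001111" contains assays A1, A11, A12, A13 and A14.

#' Construct a subset model from a membership vector
#'
#' @param membership Integer/logical vector of length 14, one entry per assay
#'   (A1 first), 1 marking membership.
#' @return An object of class `subset_model` with fields `name`, `membership`
#'   (named 0/1 integer vector) and `size`.
#' @export
new_subset_model <- function(membership) {
  membership <- as.integer(membership)
  if (length(membership) != N_ASSAYS || !all(membership %in% c(0L, 1L))) {
    stop("membership must be a length-", N_ASSAYS, " vector of 0/1 values")
  }
  names(membership) <- assay_ids()
  structure(
    list(name = paste0("A", paste(membership, collapse = "")),
         membership = membership,
         size = sum(membership)),
    class = "subset_model"
  )
}

#' Parse a subset-model nomenclature string
#'
#' Parses names of the form `"A" + 14 binary characters`, where the i-th
#' character after the leading `"A"` marks the membership of assay Ai.
#'
#' @param name A single nomenclature string, e.g. `"A10000000001111"`.
#' @return A [new_subset_model()] object.
#' @export
#' @examples
#' m <- parse_model_name("A10000000001111")
#' m$size                # 5
#' names(which(m$membership == 1))  # A1, A11, A12, A13, A14
parse_model_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("model name must be a single character string")
  }
  if (nchar(name) != N_ASSAYS + 1L) {
    stop(sprintf(
      "malformed model name '%s': expected 'A' followed by %d binary characters (length %d), got length %d",
      name, N_ASSAYS, N_ASSAYS + 1L, nchar(name)
    ))
  }
  if (substr(name, 1L, 1L) != "A") {
    stop(sprintf(
      "malformed model name '%s': position 1 must be the leading 'A', got '%s'",
      name, substr(name, 1L, 1L)
    ))
  }
  chars <- strsplit(substring(name, 2L), "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c("0", "1")))
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed model name '%s': non-binary character '%s' at position %d",
      name, chars[bad[1L]], bad[1L] + 1L
    ))
  }
  new_subset_model(as.integer(chars))
}

#' Format a subset model as its nomenclature string
#'
#' Inverse of [parse_model_name()]: `parse_model_name(format_model_name(m))`
#' recovers `m`.
#'
#' @param model A `subset_model`, a membership vector, or a name string.
#' @return The nomenclature string.
#' @export
format_model_name <- function(model) {
  as_subset_model(model)$name
}

#' Coerce to a subset model
#'
#' @param x A `subset_model`, a nomenclature string, or a length-14 0/1 vector.
#' @return A `subset_model`.
#' @export
as_subset_model <- function(x) {
  if (inherits(x, "subset_model")) return(x)
  if (is.character(x)) return(parse_model_name(x))
  if (is.numeric(x) || is.logical(x)) return(new_subset_model(x))
  stop("cannot coerce object of class '", class(x)[1L], "' to a subset model")
}

#' @export
print.subset_model <- function(x, ...) {
  cat("AR subset model", x$name, "\n")
  cat("  assays (", x$size, "): ",
      paste(names(which(x$membership == 1L)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assays contained in a subset model
#'
#' @param model A subset model (object or name).
#' @return Character vector of assay ids, in A1..A14 order.
#' @export
model_assays <- function(model) {
  m <- as_subset_model(model)
  names(which(m$membership == 1L))
}

# Vectorized membership matrix for a character vector of model names.
# Returns an n x 14 integer matrix with colnames A1..A14 and rownames the
# model names. Validation is the same as parse_model_name but batched.
model_membership <- function(names) {
  if (length(names) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = N_ASSAYS,
                  dimnames = list(NULL, assay_ids())))
  }
  ok <- grepl(sprintf("^A[01]{%d}$", N_ASSAYS), names)
  if (!all(ok)) {
    stop("malformed model name(s): ",
         paste(utils::head(names[!ok], 5L), collapse = ", "))
  }
  m <- matrix(
    as.integer(unlist(strsplit(substring(names, 2L), "", fixed = TRUE),
                      use.names = FALSE)),
    nrow = length(names), ncol = N_ASSAYS, byrow = TRUE,
    dimnames = list(names, assay_ids())
  )
  m
}

# Integer value of the membership bit vector, A1 most significant.
model_int <- function(names) {
  strtoi(substring(names, 2L), base = 2L)
}

# popcount lookup for 14-bit integers
popcount14 <- local({
  tab <- NULL
  function(x) {
    if (is.null(tab)) {
      v <- 0:(2L^N_ASSAYS - 1L)
      cnt <- integer(length(v))
      for (b in 0:(N_ASSAYS - 1L)) cnt <- cnt + bitwAnd(bitwShiftR(v, b), 1L)
      tab <<- cnt
    }
    tab[x + 1L]
  }
})

#' Enumerate subset models
#'
#' Enumerates all subsets of the 14 assays with at least `min_size` members,
#' ordered by ascending integer value of the membership bit vector (A1 being
#' the most significant bit). With `min_size = 2` there are \eqn{2^{14}-15 =
#' 16369} such subsets including the full 14-assay model, or 16,368 without
#' it; both conventions are in common use, hence the `include_full` flag.
#'
#' @param min_size Minimum number of assays per model (2..14).
#' @param include_full Keep the full 14-assay model in the enumeration?
#' @return Character vector of nomenclature strings.
#' @export
#' @examples
#' length(enumerate_subset_models())                      # 16369
#' length(enumerate_subset_models(include_full = FALSE))  # 16368
enumerate_subset_models <- function(min_size = 2L, include_full = TRUE) {
  min_size <- as.integer(min_size)
  if (is.na(min_size) || min_size < 2L || min_size > N_ASSAYS) {
    stop("min_size must be between 2 and ", N_ASSAYS)
  }
  v <- 0:(2L^N_ASSAYS - 1L)
  sz <- popcount14(v)
  keep <- sz >= min_size
  if (!include_full) keep <- keep & sz < N_ASSAYS
  v <- v[keep]
  # zero-padded binary strings, A1 most significant
  bits <- vapply(seq_len(N_ASSAYS),
                 function(i) bitwAnd(bitwShiftR(v, N_ASSAYS - i), 1L),
                 integer(length(v)))
  if (length(v) == 1L) bits <- matrix(bits, nrow = 1L)
  do.call(paste0, c(list("A"), as.data.frame(bits)))
}

#' Size of the union of two subset models
#'
#' Counts the assays present in at least one of the two models; this is the
#' assay-battery size required to run both models.
#'
#' @param a,b Subset models (objects or nomenclature strings).
#' @return Integer union size.
#' @export
#' @examples
#' union_size("A00101011101000", "A00101000000111")  # 9
union_size <- function(a, b) {
  ma <- as_subset_model(a)$membership
  mb <- as_subset_model(b)$membership
  sum(ma == 1L | mb == 1L)
}

#' Hamming distance between two subset models
#'
#' Number of assay positions at which the two membership vectors differ;
#' equals `|a U b| - |a n b|`.
#'
#' @param a,b Subset models (objects or nomenclature strings).
#' @return Integer Hamming distance.
#' @export
#' @examples
#' hamming_distance("A00101011101000", "A00101000000111")  # 7
hamming_distance <- function(a, b) {
  ma <- as_subset_model(a)$membership
  mb <- as_subset_model(b)$membership
  sum(ma != mb)
}

#' Pathway decomposition of a subset model
#'
#' Intersects a subset model's assays with one mode's pathway: the agonist
#' pathway spans A1-A11 and the antagonist pathway A1-A6 plus A12-A14. A
#' subset model's mode-specific pathway is truncated accordingly; e.g. the
#' agonist pathway of `"A10000000001111"` is just A1 and A11.
#'
#' @param model A subset model (object or name).
#' @param mode `"agonist"` or `"antagonist"`.
#' @param roster Assay roster, see [ar_roster()].
#' @return Character vector of assay ids in the model's mode pathway.
#' @export
#' @examples
#' pathway_assays("A10000000001111", "agonist")     # A1, A11
#' pathway_assays("A10000000001111", "antagonist")  # A1, A12, A13, A14
pathway_assays <- function(model, mode = c("agonist", "antagonist"),
                           roster = ar_roster()) {
  mode <- match.arg(mode)
  validate_roster(roster)
  col <- paste0("in_", mode, "_pathway")
  path <- roster$assay[roster[[col]] == 1L]
  intersect(model_assays(model), path)
}
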