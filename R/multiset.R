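#' Label multisets
#'
#' A label multiset is the basic currency of MUL-tree cluster analysis: the
#' collection of taxon labels below a node, counted with multiplicity (one
#' count per subgenome copy). It is represented as a named integer vector of
#' positive counts, sorted by label; an empty multiset is a zero-length named
#' integer vector.
#'
#' @param labels character vector of taxon labels (repeats allowed), or a
#'   named integer/numeric vector of counts.
#' @return A named integer vector of class `label_multiset`.
#' @examples
#' label_multiset(c("x", "z", "x"))
#' label_multiset(c(a = 2, b = 1))
#' @export
label_multiset <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(!is.null(names(labels)), all(labels >= 0))
    counts <- as.integer(round(labels))
    names(counts) <- names(labels)
    counts <- counts[counts > 0L]
  } else {
    labels <- as.character(labels)
    if (length(labels) == 0L) {
      counts <- integer(0)
      names(counts) <- character(0)
    } else {
      uniq <- sort(unique(labels), method = "radix")
      counts <- vapply(uniq, function(u) sum(labels == u), integer(1))
    }
  }
  counts <- counts[sort(names(counts), method = "radix")]
  bad <- names(counts)[grepl("[\\s,():;]", names(counts), perl = TRUE)]
  if (length(bad) > 0L)
    stop("invalid taxon label(s): ", paste(bad, collapse = ", "))
  structure(counts, class = "label_multiset")
}

ms_strip <- function(x) { class(x) <- NULL; x }

#' @export
print.label_multiset <- function(x, ...) {
  cat("<label_multiset> {", ms_key(x, sep = ","), "}\n", sep = "")
  invisible(x)
}

# canonical key: labels repeated by count, sorted, joined
ms_key <- function(x, sep = "\x1f") {
  paste(rep(names(x), ms_strip(x)), collapse = sep)
}

ms_size <- function(x) sum(ms_strip(x))

# is a a sub-multiset of b?
ms_contains <- function(b, a) {
  a <- ms_strip(a); b <- ms_strip(b)
  if (length(a) == 0L) return(TRUE)
  idx <- match(names(a), names(b))
  if (anyNA(idx)) return(FALSE)
  all(b[idx] >= a)
}

# multiset difference a \ b, floored at zero
ms_diff <- function(a, b) {
  a <- ms_strip(a); b <- ms_strip(b)
  idx <- match(names(b), names(a))
  hit <- !is.na(idx)
  if (any(hit)) a[idx[hit]] <- pmax(0L, a[idx[hit]] - b[hit])
  label_multiset(a[a > 0L])
}

# m copies of a
ms_scale <- function(a, m) {
  a <- ms_strip(a)
  label_multiset(a * as.integer(m))
}

# multiset sum
ms_sum <- function(a, b) {
  a <- ms_strip(a); b <- ms_strip(b)
  all_n <- sort(unique(c(names(a), names(b))), method = "radix")
  out <- integer(length(all_n)); names(out) <- all_n
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  label_multiset(out)
}

ms_equal <- function(a, b) identical(ms_key(a), ms_key(b))

#' Read or write a leaf-label multiset file
#'
#' Plain-text format: one `label<TAB>count` pair per line (count optional,
#' default 1). Used to override the inferred target multiset `L`.
#'
#' @param path file path.
#' @return `read_label_multiset()` returns a `label_multiset`.
#' @export
read_label_multiset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  labs <- vapply(parts, `[[`, character(1), 1L)
  cnts <- vapply(parts, function(p) {
    if (length(p) >= 2L) as.integer(p[[2]]) else 1L
  }, integer(1))
  names(cnts) <- labs
  label_multiset(cnts)
}

#' @rdname read_label_multiset
#' @param x a `label_multiset`.
#' @export
write_label_multiset <- function(x, path) {
  writeLines(paste(names(x), ms_strip(x), sep = "\t"), path)
  invisible(path)
}
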