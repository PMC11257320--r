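#' Stratified bilateral + unilateral count tables
#'
#' Container for the aggregated counts of a stratified two-group design in
#' which each subject contributes either a pair of correlated binary
#' responses (bilateral subjects, 0/1/2 responding organs) or a single
#' binary response (unilateral subjects, 0/1 responding organs).
#'
#' @param n integer array of dimension \code{2 x 2 x J}: \code{n[t+1, i, j]}
#'   is the number of unilateral subjects with \code{t} (0 or 1) responding
#'   organs in group \code{i} (1 = treatment, 2 = control) of stratum
#'   \code{j}.
#' @param m integer array of dimension \code{3 x 2 x J}: \code{m[t+1, i, j]}
#'   is the number of bilateral subjects with \code{t} (0, 1 or 2)
#'   responding organs.
#' @param labels optional character vector of stratum names (length
#'   \code{J}).
#'
#' @return An object of class \code{"stratified_counts"}: a list with
#'   elements \code{J}, \code{n}, \code{m}, \code{labels} and derived
#'   margins \code{N} (unilateral subjects per stratum), \code{M}
#'   (bilateral subjects per stratum), \code{n_plus} and \code{m_plus}
#'   (\code{2 x J} per-group subject totals).
#' @export
stratified_counts <- function(n, m, labels = NULL) {
  n <- as_count_array(n, 2L, "n")
  m <- as_count_array(m, 3L, "m")
  if (dim(n)[3] != dim(m)[3])
    stop("'n' and 'm' disagree on the number of strata")
  J <- dim(n)[3]
  if (is.null(labels)) labels <- as.character(seq_len(J))
  if (length(labels) != J) stop("'labels' must have length J")
  x <- structure(
    list(J = J, n = n, m = m, labels = as.character(labels)),
    class = "stratified_counts")
  validate_counts(x)
}

# coerce to t x 2 x J integer array with basic shape checks
as_count_array <- function(a, nt, what) {
  a <- as.array(a)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3L || dim(a)[1] != nt || dim(a)[2] != 2L)
    stop(sprintf("'%s' must be a %d x 2 x J array", what, nt))
  storage.mode(a) <- "double"
  a
}

#' Validate a stratified count table
#'
#' Checks that all cells are non-negative integers and that every group is
#' observed (at least one subject) in every stratum, then attaches the
#' derived margins.
#'
#' @param x a \code{"stratified_counts"} object or a bare list with
#'   elements \code{n}, \code{m} (and optionally \code{labels}).
#' @return the validated object with margins \code{N}, \code{M},
#'   \code{n_plus}, \code{m_plus} attached.
#' @export
validate_counts <- function(x) {
  if (!is.list(x) || is.null(x$n) || is.null(x$m))
    stop("expected a list with count arrays 'n' and 'm'")
  n <- as_count_array(x$n, 2L, "n")
  m <- as_count_array(x$m, 3L, "m")
  J <- dim(n)[3]
  cells <- c(n, m)
  if (any(!is.finite(cells))) stop("non-finite count")
  if (any(cells < 0)) stop("negative count")
  if (any(abs(cells - round(cells)) > 1e-8)) stop("non-integer count")
  n_plus <- apply(n, c(2, 3), sum)      # subjects per group, unilateral
  m_plus <- apply(m, c(2, 3), sum)      # subjects per group, bilateral
  tot <- n_plus + m_plus
  if (any(tot < 1)) {
    bad <- which(tot < 1, arr.ind = TRUE)[1, ]
    stop(sprintf("empty group: no subjects in group %d of stratum %d",
                 bad[1], bad[2]))
  }
  if (J < 2)
    warning("J < 2: homogeneity tests require at least two strata")
  x$n <- n
  x$m <- m
  x$J <- J
  if (is.null(x$labels)) x$labels <- as.character(seq_len(J))
  x$N <- colSums(n_plus)
  x$M <- colSums(m_plus)
  x$n_plus <- n_plus
  x$m_plus <- m_plus
  class(x) <- "stratified_counts"
  x
}

#' Extract the counts of one stratum
#'
#' @param x a \code{"stratified_counts"} object.
#' @param j stratum index (1-based).
#' @return a list with matrices \code{n} (\code{2 x 2}) and \code{m}
#'   (\code{3 x 2}), columns indexing groups.
#' @export
stratum_counts <- function(x, j) {
  stopifnot(j >= 1, j <= x$J)
  list(n = x$n[, , j, drop = TRUE], m = x$m[, , j, drop = TRUE],
       label = x$labels[j])
}

#' @export
print.stratified_counts <- function(x, ...) {
  cat(sprintf("Stratified bilateral/unilateral counts: %d strata\n", x$J))
  for (j in seq_len(x$J)) {
    cat(sprintf("  stratum %d (%s): ", j, x$labels[j]))
    cat(sprintf("treatment m=(%s) n=(%s); control m=(%s) n=(%s)\n",
                paste(x$m[, 1, j], collapse = ","),
                paste(x$n[, 1, j], collapse = ","),
                paste(x$m[, 2, j], collapse = ","),
                paste(x$n[, 2, j], collapse = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.stratified_counts <- function(x, ...) {
  rows <- list()
  grp <- c("treatment", "control")
  for (j in seq_len(x$J)) for (i in 1:2) {
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = x$labels[j], group = grp[i], design = "unilateral",
      responses = 0:1, count = x$n[, i, j], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = x$labels[j], group = grp[i], design = "bilateral",
      responses = 0:2, count = x$m[, i, j], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a stratified count table from a delimited file
#'
#' The file must have a header row \code{stratum,group,design,responses,count}
#' (comma- or tab-separated).  \code{group} is \code{treatment}/\code{control},
#' \code{design} is \code{unilateral}/\code{bilateral}, \code{responses} is the
#' number of responding organs.  Cells absent from the file default to zero,
#' so purely bilateral or purely unilateral designs need no sentinel rows.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} (default) auto-detects comma
#'   versus tab from the header line.
#' @return a validated \code{"stratified_counts"} object; strata appear in
#'   order of first appearance in the file.
#' @export
read_counts <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("stratum", "group", "design", "responses", "count")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) stop("no records")
  df$group <- tolower(trimws(df$group))
  df$design <- tolower(trimws(df$design))
  if (!all(df$group %in% c("treatment", "control")))
    stop("unknown group label: ",
         paste(unique(setdiff(df$group, c("treatment", "control"))),
               collapse = ", "))
  if (!all(df$design %in% c("unilateral", "bilateral")))
    stop("unknown design label")
  bad_t <- df$design == "unilateral" & !(df$responses %in% 0:1) |
    df$design == "bilateral" & !(df$responses %in% 0:2)
  if (any(bad_t))
    stop("invalid responses value for design (unilateral allows 0-1, ",
         "bilateral 0-2)")
  key <- paste(df$stratum, df$group, df$design, df$responses)
  if (anyDuplicated(key))
    stop("duplicate cell rows: ", key[duplicated(key)][1])
  labels <- unique(as.character(df$stratum))
  J <- length(labels)
  n <- array(0, dim = c(2, 2, J))
  m <- array(0, dim = c(3, 2, J))
  gi <- ifelse(df$group == "treatment", 1L, 2L)
  ji <- match(as.character(df$stratum), labels)
  for (r in seq_len(nrow(df))) {
    if (df$design[r] == "unilateral")
      n[df$responses[r] + 1L, gi[r], ji[r]] <- df$count[r]
    else
      m[df$responses[r] + 1L, gi[r], ji[r]] <- df$count[r]
  }
  stratified_counts(n, m, labels)
}

#' Write a stratified count table to a delimited file
#'
#' Inverse of \code{\link{read_counts}}; writing then reading reproduces the
#' counts exactly.
#'
#' @param x a \code{"stratified_counts"} object.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Built-in clinical datasets
#'
#' Returns one of the two worked datasets shipped with the package:
#' \describe{
#'   \item{\code{"aom"}}{acute otitis media with effusion trial: cured
#'     (effusion-free) ears after a 14-day course of cefaclor (treatment)
#'     versus amoxicillin (control), in three age strata.}
#'   \item{\code{"myopia"}}{orthokeratology study of myopia control:
#'     improved eyes (axial growth < 0.3 mm) under VST (treatment) versus
#'     CRT (control) lenses, in two sex strata.  The Female CRT group has
#'     no responders, so unconstrained fitting hits the probability
#'     boundary.}
#' }
#'
#' @param name \code{"aom"} or \code{"myopia"}.
#' @return a validated \code{"stratified_counts"} object.
#' @export
or_fixture <- function(name = c("aom", "myopia")) {
  if (length(name) != 1L || !name %in% c("aom", "myopia"))
    stop("unknown fixture name; available: \"aom\", \"myopia\"")
  if (name == "aom") {
    # m rows: 0,1,2 cured ears; n rows: 0,1; columns cefaclor, amoxicillin
    m <- array(c(8, 2, 8,  11, 2, 2,
                 6, 6, 10,  3, 1, 5,
                 0, 1, 3,   1, 0, 6), dim = c(3, 2, 3))
    n <- array(c(3, 9,  2, 10,
                 24, 7, 14, 22,
                 11, 8, 11, 7), dim = c(2, 2, 3))
    labels <- c("<2 years", "2-5 years", ">=6 years")
  } else {
    m <- array(c(9, 3, 7,   7, 0, 0,
                 11, 4, 3,  6, 2, 2), dim = c(3, 2, 2))
    n <- array(c(2, 1,  0, 0,
                 1, 2,  0, 0), dim = c(2, 2, 2))
    labels <- c("Female", "Male")
  }
  stratified_counts(n, m, labels)
}

# compact fingerprint used to check that two fits refer to the same data
counts_fingerprint <- function(x) {
  paste(c(x$J, x$n, x$m), collapse = ",")
}
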