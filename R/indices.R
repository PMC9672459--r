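#' Physicochemical index sets
#'
#' An index set holds numeric property values \eqn{P_u} for every
#' dinucleotide (16) or trinucleotide (64), one column per named index. They
#' back the correlation-based encoders (PseDNC, PseKNC, PCPseDNC, PCPseTNC,
#' DAC/DCC/DACC, Moran). Tables are shipped as plain TSV under
#' `inst/extdata`; see the file headers for provenance. All encoders use the
#' standardized form (each index mapped to mean 0, population SD 1 across its
#' oligonucleotides) so that indices on different scales contribute equally.
#'
#' @param name short name for the set.
#' @param order `"di"` or `"tri"`.
#' @param table numeric matrix, rows = oligonucleotides (all 16 dinucleotides
#'   or all 64 trinucleotides, rownames required), columns = named indices.
#' @param standardized logical; whether `table` is already standardized.
#' @return An object of class `phys_index_set`.
#' @export
phys_index_set <- function(name, order = c("di", "tri"), table,
                           standardized = FALSE) {
  order <- match.arg(order)
  need <- all_oligos(if (order == "di") 2 else 3)
  if (!is.matrix(table) || is.null(rownames(table)) || is.null(colnames(table)))
    stop("`table` must be a numeric matrix with oligonucleotide rownames ",
         "and index colnames")
  if (!setequal(rownames(table), need) || nrow(table) != length(need))
    stop("a '", order, "' table must cover all ", length(need),
         " oligonucleotides exactly once")
  table <- table[need, , drop = FALSE]
  structure(list(name = name, order = order, table = table,
                 standardized = isTRUE(standardized)),
            class = "phys_index_set")
}

#' @export
print.phys_index_set <- function(x, ...) {
  cat("<phys_index_set> '", x$name, "': ", ncol(x$table), " ", x$order,
      "nucleotide index(es)", if (x$standardized) ", standardized", "\n",
      sep = "")
  invisible(x)
}

read_index_tsv <- function(file) {
  path <- system.file("extdata", file, package = "phageprom", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

index_cache <- new.env(parent = emptyenv())

#' Bundled dinucleotide index sets
#'
#' `"core6"` is the six-index helical step set (twist, tilt, roll, shift,
#' slide, rise) used by PseDNC, PseKNC, DAC/DCC/DACC and Moran by default.
#' `"phys38"` extends it to 38 columns with 32 deterministic synthetic
#' pseudo-indices (see the TSV header; it is a synthetic stand-in, not
#' literature data) and is the default for PCPseDNC.
#'
#' @param set which bundled set to load.
#' @param standardized return the standardized form (default TRUE).
#' @return A [phys_index_set()].
#' @export
dinucleotide_indices <- function(set = c("core6", "phys38"),
                                 standardized = TRUE) {
  set <- match.arg(set)
  key <- paste0("di_", set, "_", standardized)
  if (!is.null(index_cache[[key]])) return(index_cache[[key]])
  file <- switch(set,
    core6 = "dinucleotide_indices_core6.tsv",
    phys38 = "dinucleotide_indices_38_synthetic.tsv")
  iset <- phys_index_set(set, "di", read_index_tsv(file))
  if (standardized) iset <- standardize_indices(iset)
  index_cache[[key]] <- iset
  iset
}

#' Bundled trinucleotide index set
#'
#' Constructed from the six dinucleotide step parameters: the value of a
#' trinucleotide XYZ under each index is the mean of the values of its two
#' constituent steps XY and YZ. This is a package construction (documented,
#' deterministic), used by PCPseTNC by default.
#'
#' @param standardized return the standardized form (default TRUE).
#' @return A [phys_index_set()] of order `"tri"`.
#' @export
trinucleotide_indices <- function(standardized = TRUE) {
  key <- paste0("tri_core6_", standardized)
  if (!is.null(index_cache[[key]])) return(index_cache[[key]])
  di <- read_index_tsv("dinucleotide_indices_core6.tsv")
  tris <- all_oligos(3)
  m <- (di[substr(tris, 1, 2), , drop = FALSE] +
        di[substr(tris, 2, 3), , drop = FALSE]) / 2
  rownames(m) <- tris
  iset <- phys_index_set("tri_core6", "tri", m)
  if (standardized) iset <- standardize_indices(iset)
  index_cache[[key]] <- iset
  iset
}

#' Standardize a physicochemical index set
#'
#' Maps every index (column) to mean 0 and population standard deviation 1
#' across its 16 or 64 oligonucleotides. Idempotent; a constant index is an
#' error (it carries no information and would divide by zero).
#'
#' @param iset a [phys_index_set()].
#' @return The standardized [phys_index_set()].
#' @export
standardize_indices <- function(iset) {
  stopifnot(inherits(iset, "phys_index_set"))
  m <- iset$table
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  if (any(sd_pop == 0))
    stop("constant index cannot be standardized: ",
         paste(colnames(m)[sd_pop == 0], collapse = ", "))
  iset$table <- sweep(sweep(m, 2, mu), 2, sd_pop, "/")
  iset$standardized <- TRUE
  iset
}
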