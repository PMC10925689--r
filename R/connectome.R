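#' Structural connectome objects
#'
#' A `connectome` bundles an N x N nonnegative weight matrix with node labels,
#' hemisphere tags and optional named focus-node subsets. The orientation is
#' fixed package-wide: the entry in row `j`, column `i` is the weight of the
#' directed connection *from* node `i` *to* node `j`. Column `i` therefore
#' holds the outgoing connections of node `i` and row `i` its incoming ones.
#'
#' @param weights numeric N x N matrix, nonnegative with a zero diagonal.
#' @param labels character vector of N unique node names. Defaults to
#'   `node_0 ... node_{N-1}`.
#' @param hemisphere character vector of per-node tags, each `"R"` or `"L"`.
#'   Defaults to the first-half-right / second-half-left convention used by
#'   mirrored two-hemisphere atlases.
#' @param focus_nodes optional named list of integer index vectors marking
#'   focus subnetworks (e.g. a hippocampus-like triplet per hemisphere).
#'
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, labels = NULL, hemisphere = NULL,
                       focus_nodes = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(labels)) labels <- paste0("node_", seq_len(n) - 1L)
  if (is.null(hemisphere)) {
    hemisphere <- rep(c("R", "L"), c(ceiling(n / 2), floor(n / 2)))
  }
  dimnames(weights) <- list(labels, labels)
  obj <- structure(
    list(weights = weights, labels = labels,
         hemisphere = hemisphere, focus_nodes = focus_nodes),
    class = "connectome"
  )
  validate_connectome(obj)
}

#' Validate a connectome
#'
#' Checks the class invariants: square nonnegative weights, exactly zero
#' diagonal, unique labels, and hemisphere tags in `{L, R}`.
#'
#' @param C a `connectome`.
#' @param force_zero_diagonal if `TRUE`, a nonzero diagonal is zeroed with a
#'   warning instead of raising an error.
#' @return The (possibly repaired) connectome, invisibly classed.
#' @export
validate_connectome <- function(C, force_zero_diagonal = FALSE) {
  w <- C$weights
  if (!is.numeric(w) || nrow(w) != ncol(w))
    stop("connectome weights must be a square numeric matrix", call. = FALSE)
  if (anyNA(w)) stop("connectome weights contain missing values", call. = FALSE)
  if (any(w < 0)) stop("connectome weights must be nonnegative", call. = FALSE)
  if (any(diag(w) != 0)) {
    if (force_zero_diagonal) {
      warning("nonzero diagonal entries set to zero (no self-connections)")
      diag(w) <- 0
      C$weights <- w
    } else {
      stop("connectome diagonal must be zero (no self-connections)",
           call. = FALSE)
    }
  }
  n <- nrow(w)
  if (length(C$labels) != n || anyDuplicated(C$labels))
    stop("labels must be unique and match the matrix dimension", call. = FALSE)
  if (length(C$hemisphere) != n || !all(C$hemisphere %in% c("L", "R")))
    stop("hemisphere tags must be 'L' or 'R', one per node", call. = FALSE)
  if (!is.null(C$focus_nodes)) {
    ok <- vapply(C$focus_nodes, function(ix) all(ix >= 1 & ix <= n), logical(1))
    if (!all(ok)) stop("focus_nodes indices out of range", call. = FALSE)
  }
  C
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  cat(sprintf("<connectome> %d nodes (%d R / %d L), %d positive edges, max weight %.4g\n",
              n, sum(x$hemisphere == "R"), sum(x$hemisphere == "L"),
              sum(x$weights > 0), max(x$weights)))
  if (!is.null(x$focus_nodes))
    cat("focus subsets:", paste(names(x$focus_nodes), collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes in a connectome
#' @param C a `connectome`.
#' @return integer node count.
#' @export
n_nodes <- function(C) nrow(C$weights)

#' Read a connectome from delimited text
#'
#' Reads a square numeric matrix from CSV/TSV, optionally with a header row
#' and a first column of labels, and validates it. If a JSON sidecar
#' `<path>.json` (as written by [write_connectome()]) exists, labels,
#' hemisphere tags and focus annotations are taken from it.
#'
#' @param path file path to the delimited matrix.
#' @param delim field delimiter; guessed from the extension by default.
#' @param force_zero_diagonal zero out a nonzero diagonal instead of erroring.
#' @return A `connectome`.
#' @export
read_connectome <- function(path, delim = NULL, force_zero_diagonal = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim))
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  raw <- utils::read.table(path, sep = delim, header = has_header,
                           row.names = if (has_header) 1L else NULL,
                           check.names = FALSE)
  w <- as.matrix(raw)
  if (!is.numeric(w)) stop("matrix file contains non-numeric fields", call. = FALSE)
  if (nrow(w) != ncol(w))
    stop(sprintf("matrix is not square (%d x %d)", nrow(w), ncol(w)),
         call. = FALSE)
  labels <- if (has_header) rownames(w) else NULL
  hemisphere <- NULL
  focus <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$labels)) labels <- meta$labels
    if (!is.null(meta$hemisphere)) hemisphere <- meta$hemisphere
    if (!is.null(meta$focus_nodes))
      focus <- lapply(meta$focus_nodes, as.integer)
  }
  obj <- structure(
    list(weights = w,
         labels = if (is.null(labels)) paste0("node_", seq_len(nrow(w)) - 1L) else labels,
         hemisphere = if (is.null(hemisphere))
           rep(c("R", "L"), c(ceiling(nrow(w) / 2), floor(nrow(w) / 2)))
         else hemisphere,
         focus_nodes = focus),
    class = "connectome"
  )
  dimnames(obj$weights) <- list(obj$labels, obj$labels)
  validate_connectome(obj, force_zero_diagonal = force_zero_diagonal)
}

#' Write a connectome to delimited text
#'
#' Writes the weight matrix as delimited decimal text at full double
#' precision (17 significant digits, so a read/write round trip is
#' bit-exact) plus a JSON sidecar `<path>.json` carrying labels, hemisphere
#' tags and focus annotations.
#'
#' @param C a `connectome`.
#' @param path output file path; the sidecar is written next to it.
#' @param delim field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(C, path, delim = ",") {
  validate_connectome(C)
  lines <- apply(C$weights, 1L, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = delim))
  writeLines(lines, path)
  meta <- list(labels = C$labels, hemisphere = C$hemisphere)
  if (!is.null(C$focus_nodes)) meta$focus_nodes <- C$focus_nodes
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Mirror a right hemisphere into a two-hemisphere connectome
#'
#' Assembles a `2n`-node connectome from the within-hemisphere block `W_rr`
#' and the cross-hemisphere block `W_rl`, imposing the lateral symmetry
#' L-L = R-R and L-R = R-L found in mirrored mouse atlases. With rows as
#' targets and columns as sources, the block layout is
#' `[[R-R, R-L], [L-R, L-L]]`, i.e. `W_rl[j, i]` is the weight from left
#' node `i` to right node `j`.
#'
#' @param W_rr n x n within-hemisphere block (zero diagonal).
#' @param W_rl n x n cross-hemisphere block.
#' @param labels_r optional right-hemisphere labels; left labels are derived
#'   by swapping an `r`/`r_` prefix to `l`/`l_` (or prefixing `l `).
#' @param focus_r optional integer indices (into the right hemisphere) of a
#'   focus subnetwork; recorded for both hemispheres.
#' @return A `2n`-node `connectome`.
#' @export
mirror_right_hemisphere <- function(W_rr, W_rl, labels_r = NULL,
                                    focus_r = NULL) {
  W_rr <- as.matrix(W_rr)
  W_rl <- as.matrix(W_rl)
  n <- nrow(W_rr)
  if (ncol(W_rr) != n || nrow(W_rl) != n || ncol(W_rl) != n)
    stop("hemisphere blocks must be square matrices of equal size",
         call. = FALSE)
  if (any(diag(W_rr) != 0))
    stop("within-hemisphere block must have a zero diagonal", call. = FALSE)
  if (any(W_rr < 0) || any(W_rl < 0))
    stop("hemisphere blocks must be nonnegative", call. = FALSE)
  if (is.null(labels_r)) labels_r <- paste0("r_node_", seq_len(n) - 1L)
  labels_l <- mirror_labels(labels_r)
  W <- rbind(cbind(W_rr, W_rl), cbind(W_rl, W_rr))
  focus <- NULL
  if (!is.null(focus_r)) {
    focus <- list(right_focus = as.integer(focus_r),
                  left_focus = as.integer(focus_r) + n)
  }
  connectome(W, labels = c(labels_r, labels_l),
             hemisphere = rep(c("R", "L"), each = n),
             focus_nodes = focus)
}

mirror_labels <- function(labels_r) {
  out <- sub("^r_", "l_", labels_r)
  plain <- out == labels_r
  out[plain] <- sub("^r ", "l ", labels_r[plain])
  still <- out == labels_r
  out[still] <- paste0("l ", labels_r[still])
  out
}

#' Randomize connectome weights
#'
#' Draws each positive weight independently from
#' `Normal(c_ji, rel_std * c_ji)`; a negative draw is replaced by the
#' original weight, zero entries (including the diagonal) stay exactly zero.
#' Used to produce surrogate connectome ensembles around a reference matrix.
#'
#' @param C a `connectome`.
#' @param rel_std relative standard deviation (default 0.1).
#' @param seed integer seed; the same seed reproduces the draw bit-exactly.
#' @return A new `connectome` with perturbed weights.
#' @export
randomize_weights <- function(C, rel_std = 0.1, seed = 1L) {
  validate_connectome(C)
  if (rel_std < 0) stop("rel_std must be nonnegative", call. = FALSE)
  w <- C$weights
  pos <- which(w > 0)
  if (length(pos) && rel_std > 0) {
    old <- w[pos]
    drawn <- with_seed_local(seed, stats::rnorm(length(old), mean = old,
                                                sd = rel_std * old))
    drawn[drawn < 0] <- old[drawn < 0]
    w[pos] <- drawn
  }
  out <- C
  out$weights <- w
  validate_connectome(out)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed_local <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
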