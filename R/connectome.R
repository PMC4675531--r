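#' Construct and validate a subject connectome
#'
#' Bundles one subject's structural data: an 82x82 symmetric matrix of
#' streamline counts `S`, the matching matrix of mean fibre lengths `L`
#' (millimetres), and the 82-vector of regional surface areas (square
#' millimetres), together with subject metadata.
#'
#' Validation enforces the structural invariants the rest of the package
#' relies on: symmetry and zero diagonals for `S` and `L`, non-negative
#' integer counts, fibre lengths strictly positive exactly where a
#' connection exists, and strictly positive surface areas.
#'
#' @param subject_id character scalar.
#' @param group `"patient"` or `"control"`.
#' @param S 82x82 matrix of non-negative integer streamline counts.
#' @param L 82x82 matrix of mean fibre lengths in mm.
#' @param areas numeric vector of 82 regional surface areas in mm^2.
#' @param atlas atlas table; defaults to [load_atlas()].
#' @return An object of class `connectome`.
#' @export
connectome <- function(subject_id, group = c("control", "patient"),
                       S, L, areas, atlas = load_atlas()) {
  group <- match.arg(group)
  obj <- structure(
    list(subject_id = as.character(subject_id), group = group,
         S = S, L = L, areas = areas, atlas = atlas),
    class = "connectome"
  )
  validate_connectome(obj)
}

#' @rdname connectome
#' @param x a `connectome` object.
#' @export
validate_connectome <- function(x) {
  n <- nrow(x$atlas)
  fail <- function(...) stop("invalid connectome '", x$subject_id, "': ",
                             ..., call. = FALSE)
  for (nm in c("S", "L")) {
    m <- x[[nm]]
    if (!is.matrix(m) || !all(dim(m) == n)) {
      fail(nm, " must be a ", n, "x", n, " matrix, got ",
           paste(dim(m), collapse = "x"))
    }
  }
  if (length(x$areas) != n) fail("areas must have length ", n)
  bad <- which(x$S != t(x$S), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- min(bad[1, ]); j <- max(bad[1, ])
    fail("S is asymmetric at cell (", i, ",", j, "): ",
         x$S[i, j], " vs ", x$S[j, i])
  }
  bad <- which(abs(x$L - t(x$L)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    fail("L is asymmetric at cell (", bad[1, 1], ",", bad[1, 2], ")")
  }
  if (any(diag(x$S) != 0) || any(diag(x$L) != 0)) {
    fail("S and L must have zero diagonals")
  }
  neg <- which(x$S < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    fail("negative streamline count at cell (", min(neg[1, ]), ",",
         max(neg[1, ]), ")")
  }
  if (any(x$S != round(x$S))) fail("streamline counts must be integers")
  if (any(x$L < 0)) fail("negative fibre length")
  mismatch <- which((x$S > 0) != (x$L > 0), arr.ind = TRUE)
  if (nrow(mismatch) > 0L) {
    fail("fibre length/count support mismatch at cell (",
         mismatch[1, 1], ",", mismatch[1, 2],
         "): L must be > 0 exactly where S > 0")
  }
  if (any(x$areas <= 0)) {
    fail("surface area must be strictly positive (region ",
         which(x$areas <= 0)[1], ")")
  }
  dimnames(x$S) <- dimnames(x$L) <- list(x$atlas$label, x$atlas$label)
  names(x$areas) <- x$atlas$label
  x
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> subject", x$subject_id, "(", x$group, ")\n")
  cat("  edges:", sum(x$S[upper.tri(x$S)] > 0),
      " total streamlines:", sum(x$S) / 2, "\n")
  cat("  fibre length range (mm):",
      paste(signif(range(x$L[x$S > 0]), 4), collapse = " - "), "\n")
  cat("  surface area range (mm^2):",
      paste(signif(range(x$areas), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Write a connectome to a directory
#'
#' Writes the tab-separated file set `S.tsv`, `L.tsv`, `areas.tsv` and
#' `meta.tsv`. Matrices carry one header row and one header column of atlas
#' labels, so the files are self-describing and diffable. The round trip
#' through [read_connectome()] reproduces integer counts exactly and
#' lengths/areas to full printed precision (15 significant digits).
#'
#' @param x a `connectome`.
#' @param dir_path directory to write into (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_connectome <- function(x, dir_path) {
  x <- validate_connectome(x)
  ok <- dir.exists(dir_path) || dir.create(dir_path, recursive = TRUE,
                                           showWarnings = FALSE)
  if (!ok || file.access(dir_path, 2L) != 0L) {
    stop("cannot write to directory: ", dir_path)
  }
  write_mat <- function(m, file, digits = NA) {
    df <- as.data.frame(if (is.na(digits)) m else signif(m, digits))
    df <- cbind(region = rownames(m), df)
    write.table(df, file.path(dir_path, file), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_mat(x$S, "S.tsv")
  write_mat(format(x$L, digits = 15, trim = TRUE, scientific = FALSE),
            "L.tsv")
  areas <- data.frame(region = names(x$areas),
                      area = format(x$areas, digits = 15, trim = TRUE,
                                    scientific = FALSE))
  write.table(areas, file.path(dir_path, "areas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(key = c("subject_id", "group"),
                     value = c(x$subject_id, x$group))
  write.table(meta, file.path(dir_path, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir_path)
}

#' Read a connectome file set
#'
#' Reads the file set produced by [write_connectome()], validates it, and
#' normalizes row/column order to atlas order. Malformed input (wrong
#' dimensions, unknown labels, asymmetric counts, negative entries) raises a
#' validation error naming the offending cell.
#'
#' @param dir_path directory containing `S.tsv`, `L.tsv`, `areas.tsv`,
#'   `meta.tsv`.
#' @param atlas atlas table; defaults to [load_atlas()].
#' @return A validated `connectome`.
#' @export
read_connectome <- function(dir_path, atlas = load_atlas()) {
  need <- file.path(dir_path, c("S.tsv", "L.tsv", "areas.tsv", "meta.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) stop("missing file(s): ",
                                 paste(missing, collapse = ", "))
  read_mat <- function(file) {
    df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
    labs <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(m) != nrow(atlas) || ncol(m) != nrow(atlas)) {
      stop("dimension mismatch in ", basename(file), ": expected ",
           nrow(atlas), "x", nrow(atlas), ", got ",
           nrow(m), "x", ncol(m))
    }
    unknown <- setdiff(c(labs, colnames(m)), atlas$label)
    if (length(unknown) > 0L) {
      stop("unknown region label(s) in ", basename(file), ": ",
           paste(head(unknown, 3), collapse = ", "))
    }
    storage.mode(m) <- "double"
    rownames(m) <- labs
    # normalize to atlas order
    m[atlas$label, atlas$label]
  }
  S <- read_mat(need[1])
  L <- read_mat(need[2])
  adf <- read.delim(need[3], stringsAsFactors = FALSE)
  unknown <- setdiff(adf$region, atlas$label)
  if (length(unknown) > 0L) {
    stop("unknown region label(s) in areas.tsv: ",
         paste(head(unknown, 3), collapse = ", "))
  }
  areas <- adf$area[match(atlas$label, adf$region)]
  if (anyNA(areas)) stop("areas.tsv does not cover all atlas regions")
  meta <- read.delim(need[4], stringsAsFactors = FALSE)
  kv <- setNames(as.character(meta$value), meta$key)
  if (!all(c("subject_id", "group") %in% names(kv))) {
    stop("meta.tsv must define subject_id and group")
  }
  connectome(kv[["subject_id"]], kv[["group"]], S, L, areas, atlas)
}
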