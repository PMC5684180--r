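# Serialization and image input --------------------------------------------

#' Write a memory set to CSV with a JSON sidecar
#'
#' The CSV holds one row per pattern (integer levels, no header mangling);
#' the sidecar `<file>.json` records N, q, M, labels and the generator
#' parameters, so the set round-trips exactly.
#'
#' @param x a `memory_set`.
#' @param file CSV path; the sidecar is written next to it.
#' @return `file`, invisibly.
#' @export
write_memory_set <- function(x, file) {
  stopifnot(inherits(x, "memory_set"))
  write.table(x$levels, file, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(n_neurons = n_neurons(x), n_memories = n_memories(x),
               n_levels = x$n_levels, labels = x$labels,
               generator = attr(x, "generator"))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' Read a memory set written by [write_memory_set()]
#'
#' @param file CSV path (sidecar `<file>.json` must be present).
#' @return A `memory_set`.
#' @export
read_memory_set <- function(file) {
  meta <- jsonlite::fromJSON(paste0(file, ".json"))
  lv <- as.matrix(read.csv(file, header = FALSE))
  dimnames(lv) <- NULL
  ms <- memory_set(lv, meta$n_levels, labels = meta$labels)
  if (!is.null(meta$generator)) attr(ms, "generator") <- meta$generator
  ms
}

#' Write / read a trained network (dense CSV + JSON sidecar)
#'
#' @param net a `hopfield_network`.
#' @param file CSV path for the dense weight matrix.
#' @return `file` invisibly (write) or a `hopfield_network` (read).
#' @export
write_network <- function(net, file) {
  stopifnot(inherits(net, "hopfield_network"))
  write.table(net$weights, file, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_neurons = net$n_neurons, n_levels = net$n_levels,
                            level_values = net$level_values,
                            center = net$center),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  meta <- jsonlite::fromJSON(paste0(file, ".json"))
  w <- as.matrix(read.csv(file, header = FALSE))
  dimnames(w) <- NULL
  structure(list(weights = w, n_neurons = meta$n_neurons,
                 n_levels = meta$n_levels,
                 level_values = as.numeric(meta$level_values),
                 center = as.numeric(meta$center)),
            class = "hopfield_network")
}

#' Read a PGM (P2 or P5) grayscale image
#'
#' @param path path to a portable graymap file.
#' @return A numeric matrix of intensities rescaled to \[0, 255\].
#' @export
read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(raw[1:min(2L, length(raw))])
  if (!txt %in% c("P2", "P5")) stop("not a PGM (P2/P5) file: ", path)
  if (txt == "P2") {
    body <- rawToChar(raw)
    body <- gsub("#[^\n]*", "", body)          # strip comments
    tok <- scan(text = body, what = character(), quiet = TRUE)
    vals <- as.numeric(tok[-1])
    w <- vals[1]; h <- vals[2]; maxval <- vals[3]
    px <- vals[-(1:3)]
    if (length(px) != w * h) stop("malformed P2 payload")
    return(matrix(px, nrow = h, byrow = TRUE) * 255 / maxval)
  }
  # P5: parse header tokens byte-wise (whitespace/comment aware), then binary
  i <- 3L; fields <- numeric(0)
  while (length(fields) < 3L) {
    while (i <= length(raw) && rawToChar(raw[i]) %in% c(" ", "\t", "\n", "\r")) i <- i + 1L
    if (i <= length(raw) && rawToChar(raw[i]) == "#") {
      while (i <= length(raw) && rawToChar(raw[i]) != "\n") i <- i + 1L
      next
    }
    j <- i
    while (j <= length(raw) && !(rawToChar(raw[j]) %in% c(" ", "\t", "\n", "\r"))) j <- j + 1L
    fields <- c(fields, as.numeric(rawToChar(raw[i:(j - 1L)])))
    i <- j
  }
  i <- i + 1L  # single whitespace after maxval
  w <- fields[1]; h <- fields[2]; maxval <- fields[3]
  if (maxval > 255) stop("16-bit PGM not supported")
  px <- as.integer(raw[i:(i + w * h - 1L)])
  matrix(px, nrow = h, byrow = TRUE) * 255 / maxval
}

#' Read a grayscale image (PGM or PNG)
#'
#' PNG reading requires the `png` package; colour PNGs are converted to
#' grayscale by channel averaging.
#'
#' @param path image path; format chosen by extension.
#' @return A numeric intensity matrix in \[0, 255\].
#' @export
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG images requires the `png` package")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3]), drop = FALSE],
                                             c(1, 2), mean)
    return(img * 255)
  }
  stop("unsupported image format: ", ext)
}

#' Write a tidy sweep and its aggregate to CSV
#'
#' @param x a `recognition_sweep`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_sweep <- function(x, dir, prefix = "sweep") {
  stopifnot(inherits(x, "recognition_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials_csv <- file.path(dir, paste0(prefix, "_cells.csv"))
  agg_csv <- file.path(dir, paste0(prefix, "_aggregated.csv"))
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  write.csv(as.data.frame(x), trials_csv, row.names = FALSE)
  write.csv(aggregate_sweep(x), agg_csv, row.names = FALSE)
  files <- c(trials_csv, agg_csv)
  jsonlite::write_json(list(config = attr(x, "config"),
                            files = as.list(setNames(unname(tools::md5sum(files)),
                                                     basename(files)))),
                       manifest, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, manifest))
}
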