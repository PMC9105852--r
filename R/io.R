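#' Read a single-channel grey-level image
#'
#' Supports PNG (8-bit, via the `png` package) and binary PGM (P5, one- or
#' two-byte samples, so 12-bit data in a 16-bit container round-trips).
#' Multi-channel images are rejected.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @param fmax declared maximum grey level of the data (default 255). PGM
#'   maxval and pixel values are validated against it.
#' @return a [GreyImage-class].
#' @seealso [writeGreyImage()], [loadDataset()]
#' @export
readGreyImage <- function(path, fmax = 255L) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  fmax <- as.integer(fmax)
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2L) {
      .stopf("%s: expected a single-channel image, found %d channels",
             path, dim(img)[3])
    }
    cmax <- if (fmax <= 255L) 255 else 65535
    px <- round(img * cmax)
  } else if (ext == "pgm") {
    px <- .readPGM(path)
  } else {
    .stopf("%s: unsupported image format '%s' (use png or pgm)", path, ext)
  }
  if (max(px) > fmax) {
    .stopf("%s: pixel values exceed declared fmax=%d (max found %d)",
           path, fmax, max(px))
  }
  greyImage(px, fmax)
}

#' Write a single-channel grey-level image
#'
#' 8-bit data (`fmax <= 255`) may be written as PNG or PGM; deeper data
#' (e.g. 12-bit) is written as binary PGM with two-byte big-endian samples,
#' since the available PNG writer is 8-bit only.
#'
#' @param image a [GreyImage-class].
#' @param path destination ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
writeGreyImage <- function(image, path) {
  stopifnot(is(image, "GreyImage"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (image@fmax > 255L) {
      .stopf("PNG output is 8-bit only; write fmax=%d data as .pgm", image@fmax)
    }
    png::writePNG(pixels(image) / 255, path)
  } else if (ext == "pgm") {
    .writePGM(pixels(image), image@fmax, path)
  } else {
    .stopf("%s: unsupported image format '%s' (use png or pgm)", path, ext)
  }
  invisible(path)
}

# Binary PGM (P5). Two-byte samples are big-endian per the netpbm spec.
.readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) .stopf("%s: truncated PGM header", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- readToken()
  if (magic != "P5") .stopf("%s: not a binary PGM (magic '%s')", path, magic)
  w <- as.integer(readToken())
  h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  nbytes <- if (maxval > 255L) 2L else 1L
  raw <- readBin(con, "integer", n = w * h, size = nbytes, signed = FALSE,
                 endian = "big")
  if (length(raw) != w * h) .stopf("%s: truncated PGM pixel data", path)
  matrix(raw, nrow = h, ncol = w, byrow = TRUE)
}

.writePGM <- function(px, fmax, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(px), nrow(px), fmax), con,
            eos = NULL)
  nbytes <- if (fmax > 255L) 2L else 1L
  writeBin(as.integer(t(px)), con, size = nbytes, endian = "big")
  invisible(path)
}

#' Load a labelled ROI dataset from disk
#'
#' Accepts either a directory containing a `manifest.csv` (columns `id`,
#' `label`, `file`, paths relative to the directory), or a directory with
#' `normal/` and `cirrhosis/` subdirectories of images (file names become
#' ids). Fails fast, naming the offending file, on unreadable images, wrong
#' channel counts, size or fmax mismatches, and duplicate ids. Images are
#' ordered by manifest row (manifest layout) or by class then file name.
#'
#' @param root dataset directory.
#' @param fmax declared maximum grey level (default 255).
#' @param size expected image side; defaults to the first image's side.
#' @return a [LabeledDataset-class].
#' @export
loadDataset <- function(root, fmax = 255L, size = NULL) {
  if (!dir.exists(root)) .stopf("dataset directory not found: %s", root)
  manifestPath <- file.path(root, "manifest.csv")
  if (file.exists(manifestPath)) {
    man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
    need <- c("id", "label", "file")
    if (!all(need %in% names(man))) {
      .stopf("%s: manifest must have columns %s", manifestPath,
             paste(need, collapse = ", "))
    }
  } else {
    files <- unlist(lapply(ROI_CLASSES, function(cl) {
      fs <- sort(list.files(file.path(root, cl), pattern = "\\.(png|pgm)$",
                            ignore.case = TRUE))
      if (length(fs)) file.path(cl, fs) else character(0)
    }))
    if (length(files) == 0L) {
      .stopf("%s: no manifest.csv and no images under normal/ or cirrhosis/", root)
    }
    man <- data.frame(id = tools::file_path_sans_ext(basename(files)),
                      label = dirname(files), file = files,
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(man$id)) {
    .stopf("duplicate ids in manifest: %s",
           paste(unique(man$id[duplicated(man$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(man$label), ROI_CLASSES)
  if (length(bad)) .stopf("unknown labels in manifest: %s", paste(bad, collapse = ", "))
  imgs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- file.path(root, man$file[i])
    img <- readGreyImage(p, fmax = fmax)
    d <- dim(img)
    if (is.null(size)) size <- d[1]
    if (d[1] != size || d[2] != size) {
      .stopf("%s: expected %dx%d image, found %dx%d", p, size, size, d[1], d[2])
    }
    imgs[[i]] <- img
  }
  labeledDataset(imgs, labels = man$label, ids = man$id, fmax = fmax)
}

#' Write a labelled ROI dataset to disk
#'
#' Creates `normal/` and `cirrhosis/` subdirectories of images named by id,
#' a `manifest.csv` (id, label, file) and a `dataset.json` recording size,
#' fmax and class counts. Round-trips through [loadDataset()] with
#' byte-identical pixels.
#'
#' @param dataset a [LabeledDataset-class].
#' @param root destination directory (created if missing).
#' @param format `"png"` (8-bit data only) or `"pgm"`.
#' @param config optional [SyntheticConfig-class] whose resolved values are
#'   stored alongside the data.
#' @return `root`, invisibly.
#' @export
writeDataset <- function(dataset, root, format = c("png", "pgm"), config = NULL) {
  stopifnot(is(dataset, "LabeledDataset"))
  format <- match.arg(format)
  if (format == "png" && fmaxLevel(dataset) > 255L) {
    .stopf("PNG output is 8-bit only; use format = 'pgm' for fmax=%d data",
           fmaxLevel(dataset))
  }
  for (cl in ROI_CLASSES) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
  }
  labs <- as.character(roiLabels(dataset))
  files <- file.path(labs, sprintf("%s.%s", roiIds(dataset), format))
  for (i in seq_len(nImages(dataset))) {
    writeGreyImage(getImage(dataset, i), file.path(root, files[i]))
  }
  utils::write.csv(data.frame(id = roiIds(dataset), label = labs, file = files,
                              stringsAsFactors = FALSE),
                   file.path(root, "manifest.csv"), row.names = FALSE)
  meta <- list(size = imageSide(dataset), fmax = fmaxLevel(dataset),
               nNormal = sum(labs == "normal"),
               nCirrhosis = sum(labs == "cirrhosis"))
  if (!is.null(config)) {
    meta$config <- list(nNormal = config@nNormal, nCirrhosis = config@nCirrhosis,
                        size = config@size, fmax = config@fmax,
                        muNormal = config@muNormal,
                        muCirrhosis = config@muCirrhosis,
                        speckleScale = config@speckleScale,
                        correlationSigma = config@correlationSigma,
                        seed = config@seed)
  }
  jsonlite::write_json(meta, file.path(root, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(root)
}

#' Write evaluation results with provenance
#'
#' Emits a CSV of per-trial error rates in long format (fixed column order:
#' `method`, `trial`, `errorRate`, `meanError`, `ciHalfwidth`, `splitHash`)
#' and a JSON sidecar carrying the summaries plus provenance: resolved
#' seeds, split hashes, package and R versions.
#'
#' @param summaries one [EvalSummary-class] or a list of them.
#' @param csvPath destination CSV path.
#' @param jsonPath destination JSON path (default: CSV path with `.json`).
#' @param config named list of run parameters to record (seeds etc.).
#' @return Invisible list of the two paths.
#' @seealso [readResults()]
#' @export
writeResults <- function(summaries, csvPath, jsonPath = NULL, config = list()) {
  if (is(summaries, "EvalSummary")) summaries <- list(summaries)
  if (length(summaries) == 0L) .stopf("no summaries to write")
  if (is.null(jsonPath)) {
    jsonPath <- paste0(tools::file_path_sans_ext(csvPath), ".json")
  }
  long <- do.call(rbind, lapply(summaries, as.data.frame))
  utils::write.csv(long, csvPath, row.names = FALSE)
  payload <- list(
    results = lapply(summaries, function(s) {
      list(method = methodId(s), perTrial = perTrialErrors(s),
           meanError = meanError(s), ciHalfwidth = ciHalfwidth(s),
           splitHash = splitHash(s), nTest = s@nTest)
    }),
    provenance = c(config, list(
      package = as.character(utils::packageVersion("ToneROI")),
      rVersion = as.character(getRversion()),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))))
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(csv = csvPath, json = jsonPath))
}

#' Re-read evaluation results written by [writeResults()]
#'
#' @param jsonPath path to the JSON sidecar.
#' @return List with `summaries` (list of [EvalSummary-class]) and
#'   `provenance` (named list).
#' @export
readResults <- function(jsonPath) {
  payload <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  res <- payload$results
  summaries <- lapply(seq_len(nrow(res)), function(i) {
    .evalSummary(res$method[i], unlist(res$perTrial[i]), res$splitHash[i],
                 res$nTest[i])
  })
  list(summaries = summaries, provenance = payload$provenance)
}
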