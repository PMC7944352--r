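# Serialization: plain-text, lexicographically sorted, lossless
# round-trips.  Bit conventions (row-major, row 0 earliest, most
# significant bit first) are fixed package-wide in R/bits.R.

fmt_num <- function(x) sprintf("%.17g", x)

#' Save / load CTM tables as TSV
#'
#' Conditional tables carry `#pair_count`, `#fallback_bits`, `#crop` and
#' `#source` header lines followed by tab-separated (condition, outcome,
#' value) rows; unconditional tables carry `#shape`/`#source` and (key,
#' value) rows.  Rows are written lexicographically sorted, so
#' save-load-save cycles are byte-identical.  Externally published CTM
#' tables can be loaded through the same format after a one-time
#' conversion to these columns.
#'
#' @param table a `cond_ctm_table` or [ctm_table()].
#' @param path file path.
#' @return `load_ctm_table()` returns the reconstructed table.
#' @export
save_ctm_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(table, "cond_ctm_table")) {
    writeLines(c("#type\tcond_ctm_table",
                 paste0("#pair_count\t", format(table$pair_count,
                                                scientific = FALSE)),
                 paste0("#fallback_bits\t", table$fallback_bits),
                 paste0("#crop\t", jsonlite::toJSON(table$crop,
                                                    auto_unbox = TRUE)),
                 paste0("#source\t", table$source)), con)
    keys <- names(table$entries)
    sp <- regexpr("|", keys, fixed = TRUE)
    writeLines(paste(substr(keys, 1L, sp - 1L),
                     substr(keys, sp + 1L, nchar(keys)),
                     fmt_num(unname(table$entries)), sep = "\t"), con)
  } else {
    writeLines(c("#type\tctm_table",
                 paste0("#shape\t", paste(table$shape, collapse = "x")),
                 paste0("#source\t", table$source)), con)
    writeLines(paste(names(table$entries), fmt_num(unname(table$entries)),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname save_ctm_table
#' @export
load_ctm_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)
  meta <- stats::setNames(
    vapply(fields, function(f) paste(f[-1L], collapse = "\t"), character(1)),
    vapply(fields, function(f) sub("^#", "", f[[1L]]), character(1)))
  rows <- strsplit(lines[!hdr], "\t", fixed = TRUE)
  mget0 <- function(k) if (k %in% names(meta)) meta[[k]] else ""
  if (!"type" %in% names(meta)) stop("missing #type header")
  type <- meta[["type"]]
  if (type == "cond_ctm_table") {
    if (!"pair_count" %in% names(meta)) {
      stop("missing #pair_count header (line ", sum(hdr) + 1L, ")")
    }
    bad <- which(vapply(rows, length, integer(1)) != 3L)
    if (length(bad)) stop("malformed row at line ", sum(hdr) + bad[1L])
    conds <- vapply(rows, `[[`, character(1), 1L)
    outs <- vapply(rows, `[[`, character(1), 2L)
    vals <- as.numeric(vapply(rows, `[[`, character(1), 3L))
    entries <- stats::setNames(vals, paste(conds, outs, sep = "|"))
    crop <- if (nzchar(mget0("crop")) && mget0("crop") != "null") {
      jsonlite::fromJSON(meta[["crop"]])
    }
    structure(list(entries = entries,
                   pair_count = as.numeric(meta[["pair_count"]]),
                   fallback_bits = as.integer(meta[["fallback_bits"]]),
                   crop = crop,
                   cond_len = nchar(conds[[1L]]), out_len = nchar(outs[[1L]]),
                   source = mget0("source"), meta = list()),
              class = "cond_ctm_table")
  } else {
    bad <- which(vapply(rows, length, integer(1)) != 2L)
    if (length(bad)) stop("malformed row at line ", sum(hdr) + bad[1L])
    keys <- vapply(rows, `[[`, character(1), 1L)
    vals <- as.numeric(vapply(rows, `[[`, character(1), 2L))
    shape <- suppressWarnings(as.integer(strsplit(mget0("shape"),
                                                  "x")[[1L]]))
    ctm_table(stats::setNames(vals, keys), shape, source = mget0("source"))
  }
}

#' Save / load labelled datasets as TSV
#'
#' One row per sample (`id`, `split`, `label`, `bits`, row-major), with
#' the sample shape and the full generator manifest in JSON header lines;
#' the manifest seed is sufficient to regenerate the dataset bit-for-bit.
#' A list of splits round-trips as one file.
#'
#' @param dataset a [labeled_dataset()] or a named list of them.
#' @param path file path.
#' @return `load_dataset()` returns a named list of `labeled_dataset`s
#'   (or a single one when the file holds a single split).
#' @export
save_dataset <- function(dataset, path) {
  splits <- if (inherits(dataset, "labeled_dataset")) {
    stats::setNames(list(dataset), dataset$split)
  } else dataset
  con <- file(path, "w")
  on.exit(close(con))
  s1 <- splits[[1L]]$samples[[1L]]
  shape <- if (is.matrix(s1)) dim(s1) else c(0L, length(s1))
  writeLines(c(paste0("#shape\t", shape[1L], "\t", shape[2L]),
               paste0("#manifest\t",
                      jsonlite::toJSON(splits[[1L]]$manifest,
                                       auto_unbox = TRUE))), con)
  writeLines("id\tsplit\tlabel\tbits", con)
  i <- 0L
  for (sp in names(splits)) {
    d <- splits[[sp]]
    for (j in seq_along(d$samples)) {
      i <- i + 1L
      writeLines(paste(i, sp, d$labels[j], tensor_key(d$samples[[j]]),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)
  meta <- stats::setNames(
    vapply(fields, function(f) paste(f[-1L], collapse = "\t"), character(1)),
    vapply(fields, function(f) sub("^#", "", f[[1L]]), character(1)))
  shape <- as.integer(strsplit(meta[["shape"]], "\t", fixed = TRUE)[[1L]])
  manifest <- jsonlite::fromJSON(meta[["manifest"]])
  body <- lines[!hdr]
  body <- body[body != "id\tsplit\tlabel\tbits"]
  rows <- strsplit(body, "\t", fixed = TRUE)
  if (any(vapply(rows, length, integer(1)) != 4L)) stop("malformed sample row")
  split <- vapply(rows, `[[`, character(1), 2L)
  label <- vapply(rows, `[[`, character(1), 3L)
  bits <- vapply(rows, `[[`, character(1), 4L)
  mk <- function(i, sp) {
    samples <- lapply(bits[i], function(s) {
      b <- as_bits(s)
      if (shape[1L] > 0L) matrix(b, shape[1L], shape[2L], byrow = TRUE) else b
    })
    labeled_dataset(samples, label[i], sp, manifest = manifest)
  }
  out <- lapply(unique(split), function(sp) mk(which(split == sp), sp))
  names(out) <- unique(split)
  if (length(out) == 1L) out[[1L]] else out
}

#' Save / load a fitted classifier as JSON
#'
#' Centroids, class order, the distance kind and its scalar settings, and
#' provenance round-trip; conditional tables are referenced by their
#' source string and re-supplied at load time.
#'
#' @param model an `apclassifier`.
#' @param path file path.
#' @param table the conditional (or base) table to re-attach on load.
#' @return `load_model()` returns the reconstructed `apclassifier`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "apclassifier"))
  if (model$type == "scalar") {
    obj <- list(type = "scalar", classes = model$classes,
                centers = as.list(model$centers))
  } else {
    obj <- list(
      type = "centroid", classes = model$classes,
      centroids = lapply(model$centroids, function(c0) {
        if (is.character(c0)) list(key = c0)
        else list(bits = bits_to_string(as_bits(c0)))
      }),
      distance = list(kind = model$distance$kind,
                      block_width = model$distance$block_width,
                      table_source = if (!is.null(model$distance$table))
                        model$distance$table$source else NULL))
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, table = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (obj$type == "scalar") {
    stop("scalar models need their scorer re-attached; rebuild with apclassifier()")
  }
  centroids <- lapply(obj$centroids, function(c0) {
    if (!is.null(c0$key)) c0$key else as_bits(c0$bits)
  })
  spec <- ap_distance(obj$distance$kind, table = table,
                      block_width = obj$distance$block_width)
  apclassifier(distance = spec, centroids = centroids,
               classes = unlist(obj$classes))
}

#' Plain PBM (P1) image IO
#'
#' @param m a 0/1 matrix.
#' @param path file path.
#' @return `read_pbm()` returns a 0/1 integer matrix.
#' @export
write_pbm <- function(m, path) {
  stopifnot(is.matrix(m))
  writeLines(c("P1", paste(ncol(m), nrow(m)),
               apply(m, 1L, paste, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_pbm
#' @export
read_pbm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1L] != "P1") stop("not a plain PBM (P1) file")
  dims <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
  matrix(vals, dims[2L], dims[1L], byrow = TRUE)
}

#' Run manifest
#'
#' Written by every CLI run: the command, its full configuration, the
#' top-level and substream seeds, table identities and output paths -
#' enough to reproduce the run bit-for-bit (wall-clock excluded).
#'
#' @param command subcommand name.
#' @param config named list of options.
#' @param seed top-level seed.
#' @param outputs character vector of output paths.
#' @param path where to write the manifest JSON (`NULL` to skip writing).
#' @return the manifest list, invisibly when written.
#' @export
run_manifest <- function(command, config, seed, outputs, path = NULL) {
  man <- list(command = command, config = config, seed = seed,
              substreams = as.list(substream_seeds(
                if (is.null(seed)) 0 else seed,
                c("dataset", "training", "attack"))),
              outputs = outputs, timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE), path)
    return(invisible(man))
  }
  man
}
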