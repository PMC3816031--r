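#' Read and write acoustic feature files
#'
#' Two dialects: `"htk"` is the HTK parameter file format (12-byte big-endian
#' header: number of samples int32, sample period int32 in 100 ns units,
#' sample size int16 in bytes, parameter kind int16; float32 samples), and
#' `"text"` is a portable whitespace container with one frame per row.
#' HTK round trips are exact within float32; text round trips are exact.
#'
#' @param features Numeric matrix, frames by dimensions.
#' @param path File path.
#' @param dialect `"text"` or `"htk"`.
#' @param samp_period Sample period in 100 ns units (default 100000 = 10 ms).
#' @param parm_kind HTK parameter-kind code (default 9, USER).
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature matrix.
#' @export
write_features <- function(features, path, dialect = c("text", "htk"),
                           samp_period = 100000L, parm_kind = 9L) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(features), nrow(features) > 0)
  if (dialect == "text") {
    lines <- apply(features, 1, function(r) {
      paste(formatC(r, format = "g", digits = 17), collapse = " ")
    })
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(nrow(features)), con, size = 4L, endian = "big")
    writeBin(as.integer(samp_period), con, size = 4L, endian = "big")
    writeBin(as.integer(4L * ncol(features)), con, size = 2L, endian = "big")
    writeBin(as.integer(parm_kind), con, size = 2L, endian = "big")
    writeBin(as.numeric(t(features)), con, size = 4L, endian = "big")
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, dialect = c("text", "htk")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") {
    lines <- readLines(path)
    rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l),
                                                          "\\s+")[[1]]))
    d <- unique(lengths(rows))
    if (length(d) != 1L) {
      stopf("ragged text feature file '%s': row lengths %s", path,
            paste(sort(d), collapse = ", "))
    }
    matrix(unlist(rows), nrow = length(rows), ncol = d, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_n <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    hdr_p <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    hdr_s <- readBin(con, "integer", 1L, size = 2L, endian = "big")
    hdr_k <- readBin(con, "integer", 1L, size = 2L, endian = "big")
    if (length(hdr_k) != 1L || is.na(hdr_n) || hdr_n < 1L || hdr_s < 4L ||
        hdr_s %% 4L != 0L) {
      stopf("malformed HTK header in '%s' (offset 0-11)", path)
    }
    d <- hdr_s %/% 4L
    vals <- readBin(con, "numeric", hdr_n * d, size = 4L, endian = "big")
    if (length(vals) != hdr_n * d) {
      stopf("truncated HTK file '%s': expected %d samples, got %d (offset %d)",
            path, hdr_n * d, length(vals), 12L + 4L * length(vals))
    }
    matrix(vals, nrow = hdr_n, ncol = d, byrow = TRUE)
  }
}

#' Read and write master label files (MLF)
#'
#' HTK-style label files: a `#!MLF!#` header, then per sentence a quoted
#' `"*/id.lab"` line, one label per line, and a `.` terminator. Empty entries
#' (a terminator immediately after the id) are preserved as empty sequences.
#'
#' @param transcriptions Named list of character vectors (sentence id to
#'   label sequence).
#' @param path File path.
#' @return `write_mlf()` returns `path` invisibly; `read_mlf()` returns the
#'   named list of label sequences.
#' @export
write_mlf <- function(transcriptions, path) {
  if (is.null(names(transcriptions)) || anyDuplicated(names(transcriptions))) {
    stopf("transcriptions must be a named list with unique sentence ids")
  }
  lines <- c("#!MLF!#", unlist(lapply(names(transcriptions), function(id) {
    c(sprintf("\"*/%s.lab\"", id), transcriptions[[id]], ".")
  })))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mlf
#' @export
read_mlf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "#!MLF!#") {
    stopf("'%s' is not an MLF (missing #!MLF!# header at line 1)", path)
  }
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    if (!grepl("^\".*\"$", lines[i])) {
      stopf("MLF parse error at line %d of '%s': expected quoted entry id",
            i, path)
    }
    id <- sub("\\.(lab|rec)\"$", "", sub("^\"(\\*/)?", "", lines[i]))
    id <- sub("\"$", "", id)
    if (id %in% names(out)) {
      stopf("duplicate sentence id '%s' at line %d of '%s'", id, i, path)
    }
    j <- i + 1L
    labels <- character(0)
    terminated <- FALSE
    while (j <= length(lines)) {
      if (lines[j] == ".") { terminated <- TRUE; break }
      labels <- c(labels, lines[j])
      j <- j + 1L
    }
    if (!terminated) {
      stopf("unterminated MLF entry '%s' starting at line %d of '%s'",
            id, i, path)
    }
    out[[id]] <- labels
    i <- j + 1L
  }
  out
}

#' Read and write plain-text pronunciation dictionaries
#'
#' One entry per line: the word followed by its phone sequence, whitespace
#' separated.
#'
#' @param lexicon An [asr_lexicon()].
#' @param path File path.
#' @return `write_lexicon()` returns `path` invisibly; `read_lexicon()`
#'   returns an [asr_lexicon()].
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- vapply(seq_len(nrow(lexicon)), function(i) {
    paste(c(lexicon$word[i], lexicon$phones[[i]]), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  short <- which(lengths(toks) < 2L)
  if (length(short) > 0L) {
    stopf("lexicon entry without pronunciation at line %d of '%s'",
          short[1], path)
  }
  asr_lexicon(vapply(toks, `[[`, character(1), 1L),
              lapply(toks, function(t) t[-1L]))
}

#' Serialize a model bank to a versioned JSON document
#'
#' Writes labels, topology specs, transition probabilities and mixture
#' parameters as plain JSON so trained banks survive a session; the format
#' is versioned for forward compatibility.
#'
#' @param model_set A [model_set()].
#' @param path File path.
#' @return `write_model_set()` returns `path` invisibly; `read_model_set()`
#'   the reconstructed [model_set()].
#' @export
write_model_set <- function(model_set, path) {
  doc <- list(
    format = "phonotop-modelset", version = 1L,
    feature_dim = model_set$feature_dim,
    variance_floor = model_set$variance_floor,
    hmms = lapply(model_set$hmms, function(h) {
      list(label = h$label, topo_type = h$spec$topo_type,
           n_states = h$spec$n_states, entry = h$entry, trans = h$trans,
           exit = h$exit,
           states = lapply(h$states, function(st) {
             list(w = st$w, mu = st$mu, var = st$var)
           }))
    })
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(doc$format, "phonotop-modelset")) {
    stopf("'%s' is not a phonotop model bank", path)
  }
  hmms <- lapply(doc$hmms, function(h) {
    hh <- phone_hmm(h$label, topology_spec(h$topo_type, h$n_states),
                    feature_dim = doc$feature_dim,
                    n_mix = length(h$states[[1]]$w))
    hh$entry <- as.numeric(h$entry)
    hh$trans <- as.matrix(h$trans)
    hh$exit <- as.numeric(h$exit)
    hh$states <- lapply(h$states, function(st) {
      list(w = as.numeric(st$w),
           mu = matrix(as.numeric(st$mu), nrow = length(st$w)),
           var = matrix(as.numeric(st$var), nrow = length(st$w)))
    })
    hh
  })
  names(hmms) <- vapply(hmms, function(h) h$label, character(1))
  structure(list(hmms = hmms, feature_dim = as.integer(doc$feature_dim),
                 variance_floor = as.numeric(doc$variance_floor)),
            class = "model_set")
}

#' Write a corpus to disk as feature files plus label files
#'
#' One feature file per sentence (chosen dialect), a word-level and a
#' phone-level MLF, and a splits CSV.
#'
#' @param corpus A [speech_corpus()].
#' @param dir Output directory (created if needed).
#' @param dialect Feature file dialect, `"text"` or `"htk"`.
#' @return The directory, invisibly.
#' @export
write_corpus <- function(corpus, dir, dialect = c("text", "htk")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "htk") "mfc" else "txt"
  for (i in seq_len(nrow(corpus))) {
    write_features(corpus$features[[i]],
                   file.path(dir, sprintf("%s.%s", corpus$id[i], ext)),
                   dialect = dialect)
  }
  write_mlf(setNames(corpus$words, corpus$id), file.path(dir, "words.mlf"))
  write_mlf(setNames(corpus$phones, corpus$id), file.path(dir, "phones.mlf"))
  utils::write.csv(data.frame(id = corpus$id, split = corpus$split),
                   file.path(dir, "splits.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Directory containing the feature files, MLFs and splits CSV.
#' @param dialect Feature file dialect used when writing.
#' @return A [speech_corpus()].
#' @export
read_corpus <- function(dir, dialect = c("text", "htk")) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "htk") "mfc" else "txt"
  words <- read_mlf(file.path(dir, "words.mlf"))
  phones <- read_mlf(file.path(dir, "phones.mlf"))
  splits <- utils::read.csv(file.path(dir, "splits.csv"),
                            stringsAsFactors = FALSE)
  ids <- names(words)
  feats <- lapply(ids, function(id) {
    read_features(file.path(dir, sprintf("%s.%s", id, ext)), dialect)
  })
  speech_corpus(ids, feats, words[ids], phones[ids],
                split = splits$split[match(ids, splits$id)])
}

#' Write a run manifest alongside outputs
#'
#' Records the configuration (and its MD5 hash), the seed, the package
#' version and the R version, so any run can be reproduced from its output
#' directory.
#'
#' @param dir Output directory.
#' @param config Any serializable configuration object.
#' @param seed The run seed.
#' @return Path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(config = jsonlite::fromJSON(cfg_json,
                                               simplifyVector = TRUE),
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("phonotop")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
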