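# Readers and writers for the package's plain-text interchange formats:
# tabular PWM blocks, MEME-minimal motifs, contact-model TSV, contact
# instances, and similarity-graph edge lists.

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

# Column-sum policy on read (see read_pwm_dataset).
.fix_columns <- function(m, renormalize, where, logger = message) {
  cs <- colSums(m)
  if (renormalize) {
    if (any(cs <= 0)) stop(sprintf("%s: column with non-positive sum", where))
    if (any(abs(cs - 1) > 1e-9))
      logger(sprintf("%s: renormalized %d column(s)", where, sum(abs(cs - 1) > 1e-9)))
    m <- sweep(m, 2, cs, "/")
  } else if (any(abs(cs - 1) > 1e-4)) {
    stop(sprintf("%s: column sums deviate from 1 by more than 1e-4 (max %.3g); set renormalize = TRUE to rescale",
                 where, max(abs(cs - 1))), call. = FALSE)
  } else if (any(abs(cs - 1) > 1e-9)) {
    logger(sprintf("%s: renormalized %d column(s) within float slack", where,
                   sum(abs(cs - 1) > 1e-9)))
    m <- sweep(m, 2, cs, "/")
  }
  m
}

#' Read a dataset of PWMs keyed by core sequence
#'
#' Two dialects are supported.  `"tabular"`: one motif per block, a header
#' line `>CORE_SEQ k=3` followed by four rows labeled A/C/G/T of k
#' tab-separated frequencies.  `"meme"`: MEME-minimal motif format (version
#' line, `ALPHABET= ACGT`, `MOTIF` blocks with a letter-probability matrix,
#' one row per position); motif identifiers must be valid core sequences.
#'
#' @param path input file.
#' @param format `"tabular"` (default) or `"meme"`.
#' @param renormalize if TRUE, columns with positive sums are rescaled to
#'   sum to 1 (the event is messaged); if FALSE, column sums may deviate
#'   from 1 by at most 1e-4 (deviations beyond 1e-9 are rescaled with a
#'   message, beyond 1e-4 are an error).
#' @param aggregate if TRUE, repeated core sequences are merged with
#'   [aggregate_by_core()]; if FALSE a duplicate is an error.
#' @param label dataset label (default the file name).
#' @return a [pwm_dataset()].
#' @export
read_pwm_dataset <- function(path, format = c("tabular", "meme"),
                             renormalize = FALSE, aggregate = FALSE,
                             label = basename(path)) {
  format <- match.arg(format)
  lines <- readLines(path)
  raw <- if (format == "tabular") .parse_tabular(path, lines)
         else .parse_meme(path, lines)
  by_core <- list()
  for (entry in raw) {
    m <- .fix_columns(entry$matrix, renormalize, sprintf("%s (motif %s)", path, entry$core))
    rownames(m) <- BASES
    validate_pwm(m)
    if (entry$core %in% names(by_core) && !aggregate)
      stop(sprintf("%s: duplicate core sequence '%s'; set aggregate = TRUE to merge",
                   path, entry$core), call. = FALSE)
    by_core[[entry$core]] <- c(by_core[[entry$core]], list(m))
  }
  pwms <- lapply(by_core, function(ms)
    if (length(ms) == 1L) ms[[1]] else aggregate_by_core(ms))
  pwm_dataset(pwms, label = label)
}

.parse_tabular <- function(path, lines) {
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, ">"))
      .parse_error(path, i, "expected a '>CORE k=...' header line")
    hdr <- strsplit(sub("^>", "", line), "[ \t]+")[[1]]
    core <- hdr[1]
    kf <- grep("^k=", hdr, value = TRUE)
    if (length(kf) != 1L) .parse_error(path, i, "header must carry a k=<int> field")
    k <- as.integer(sub("^k=", "", kf))
    if (is.na(k) || k < 1L) .parse_error(path, i, "invalid k")
    if (i + 4L > length(lines)) .parse_error(path, i, "truncated motif block")
    m <- matrix(NA_real_, 4, k)
    for (r in 1:4) {
      fields <- strsplit(trimws(lines[i + r]), "\t")[[1]]
      if (length(fields) != k + 1L || fields[1] != BASES[r])
        .parse_error(path, i + r,
                     sprintf("expected row '%s' with %d tab-separated values", BASES[r], k))
      vals <- suppressWarnings(as.numeric(fields[-1]))
      if (any(is.na(vals))) .parse_error(path, i + r, "non-numeric frequency")
      m[r, ] <- vals
    }
    out[[length(out) + 1L]] <- list(core = core, matrix = m)
    i <- i + 5L
  }
  out
}

.parse_meme <- function(path, lines) {
  out <- list(); i <- 1L; n <- length(lines)
  while (i <= n && !grepl("^MEME version", lines[i])) i <- i + 1L
  if (i > n) .parse_error(path, 1L, "missing 'MEME version' line")
  while (i <= n) {
    if (grepl("^MOTIF\\b", lines[i])) {
      core <- strsplit(trimws(lines[i]), "[ \t]+")[[1]][2]
      if (is.na(core)) .parse_error(path, i, "MOTIF line without identifier")
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", lines[j])) {
        if (grepl("^MOTIF\\b", lines[j]))
          .parse_error(path, j, "MOTIF block without a letter-probability matrix")
        j <- j + 1L
      }
      if (j > n) .parse_error(path, i, "MOTIF block without a letter-probability matrix")
      w <- suppressWarnings(as.integer(sub(".*\\bw= *([0-9]+).*", "\\1", lines[j])))
      if (is.na(w)) .parse_error(path, j, "letter-probability line must state w=")
      if (j + w > n) .parse_error(path, j, "truncated letter-probability matrix")
      m <- matrix(NA_real_, 4, w)
      for (r in seq_len(w)) {
        vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[j + r]), "[ \t]+")[[1]]))
        if (length(vals) != 4L || any(is.na(vals)))
          .parse_error(path, j + r, "expected 4 numeric probabilities")
        m[, r] <- vals                  # MEME rows are positions
      }
      out[[length(out) + 1L]] <- list(core = core, matrix = m)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  out
}

#' Write a PWM dataset
#'
#' @param dataset a [pwm_dataset()].
#' @param path output file.
#' @param format `"tabular"` or `"meme"`; see [read_pwm_dataset()].
#' @param digits significant digits written (default full precision).
#' @return `path`, invisibly.
#' @export
write_pwm_dataset <- function(dataset, path, format = c("tabular", "meme"),
                              digits = 17) {
  stopifnot(inherits(dataset, "pwm_dataset"))
  format <- match.arg(format)
  fmt <- function(x) sprintf("%.*g", digits, x)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "tabular") {
    for (core in cores(dataset)) {
      p <- dataset$pwms[[core]]
      writeLines(sprintf(">%s k=%d", core, ncol(p)), con)
      for (r in 1:4)
        writeLines(paste(c(BASES[r], fmt(p[r, ])), collapse = "\t"), con)
    }
  } else {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "Background letter frequencies",
                 "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
    for (core in cores(dataset)) {
      p <- dataset$pwms[[core]]
      writeLines(sprintf("MOTIF %s", core), con)
      writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         ncol(p)), con)
      for (j in seq_len(ncol(p)))
        writeLines(paste(fmt(p[, j]), collapse = " "), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Write / read a contact model as TSV
#'
#' Header comment lines carry the contact threshold; the table has one row
#' per aligned DBD position and one column per binding-site position.
#'
#' @param model a [contact_model()].
#' @param path file path.
#' @return `path` invisibly (write) or a `contact_model` (read).
#' @export
write_contact_model <- function(model, path) {
  stopifnot(inherits(model, "contact_model"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# contact_threshold=%.17g", model$contact_threshold), con)
  writeLines(paste(c("dbd_position", seq_len(ncol(model$M))), collapse = "\t"), con)
  for (i in seq_len(nrow(model$M)))
    writeLines(paste(c(i, sprintf("%.17g", model$M[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_contact_model
#' @export
read_contact_model <- function(path) {
  lines <- readLines(path)
  thr_line <- grep("^# contact_threshold=", lines, value = TRUE)
  thr <- if (length(thr_line)) as.numeric(sub("^# contact_threshold=", "", thr_line[1])) else 0.10
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = body, check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(M) <- NULL
  contact_model(M, contact_threshold = thr)
}

#' Read contact instances from a concatenated TSV file
#'
#' Format: for each instance, a line `>SEQUENCE` followed by one row of
#' tab-separated 0/1 flags per aligned DBD position (columns are
#' binding-site positions).
#'
#' @param path input file.
#' @return list of [contact_instance()] objects.
#' @export
read_contact_instances <- function(path) {
  lines <- readLines(path)
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, ">")) .parse_error(path, i, "expected '>SEQUENCE' line")
    seq <- sub("^>", "", line)
    nr <- nchar(seq)
    if (i + nr > length(lines)) .parse_error(path, i, "truncated contact map")
    m <- matrix(FALSE, nr, 0)
    rows <- lapply(seq_len(nr), function(r) {
      vals <- suppressWarnings(as.integer(strsplit(trimws(lines[i + r]), "\t")[[1]]))
      if (any(is.na(vals)) || any(!vals %in% c(0L, 1L)))
        .parse_error(path, i + r, "contact rows must be tab-separated 0/1 flags")
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      .parse_error(path, i + 1L, "ragged contact map")
    m <- do.call(rbind, rows) == 1L
    out[[length(out) + 1L]] <- contact_instance(seq, m)
    i <- i + nr + 1L
  }
  if (length(out) == 0L) stop(sprintf("%s: no contact instances found", path))
  out
}

#' Write / read similarity graphs as an edge-list TSV
#'
#' Columns `j`, `source_core`, `target_core`, `weight` (normalized); comment
#' header lines `# nodes j=<j>: a,b,c` preserve isolated nodes so that
#' graphs round-trip exactly.
#'
#' @param graphs list of [similarity_graph()].
#' @param path file path.
#' @return `path` invisibly (write) or a list of graphs (read).
#' @export
write_graphs <- function(graphs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (g in graphs)
    writeLines(sprintf("# nodes j=%d: %s", g$j, paste(g$nodes, collapse = ",")), con)
  writeLines("j\tsource_core\ttarget_core\tweight", con)
  for (g in graphs) {
    e <- g$edges
    if (nrow(e) > 0L)
      writeLines(sprintf("%d\t%s\t%s\t%.17g", g$j, e$from, e$to, e$weight), con)
  }
  invisible(path)
}

#' @rdname write_graphs
#' @export
read_graphs <- function(path) {
  lines <- readLines(path)
  node_lines <- grep("^# nodes j=", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  nodes_by_j <- list()
  for (nl in node_lines) {
    j <- as.integer(sub("^# nodes j=([0-9]+):.*", "\\1", nl))
    nodes_by_j[[as.character(j)]] <-
      strsplit(sub("^# nodes j=[0-9]+: *", "", nl), ",")[[1]]
  }
  js <- sort(unique(c(as.integer(names(nodes_by_j)), tab$j)))
  lapply(js, function(j) {
    e <- tab[tab$j == j, c("source_core", "target_core", "weight")]
    names(e) <- c("from", "to", "weight")
    nodes <- nodes_by_j[[as.character(j)]]
    if (is.null(nodes)) nodes <- unique(c(e$from, e$to))
    similarity_graph(j, nodes, e)
  })
}
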