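# MDL MOLFILE V2000 and SDF reading/writing.

fixed_int <- function(line, from, to) {
  s <- trimws(substr(line, from, to))
  if (s == "") return(0L)
  v <- suppressWarnings(as.integer(s))
  if (is.na(v)) stop("malformed integer field: '", s, "'", call. = FALSE)
  v
}

fixed_num <- function(line, from, to) {
  s <- trimws(substr(line, from, to))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("malformed numeric field: '", s, "'", call. = FALSE)
  v
}

#' Read an MDL MOLFILE (V2000)
#'
#' Parses the header, counts line, atom block and bond block of a V2000
#' molfile. Wedge codes 1 (up) and 6 (down) are mapped onto the bond's
#' `wedge` field with the narrow end at the first bond atom. The graph is
#' flagged 3D when any |z| exceeds 1e-4, else 2D. Charged, isotopic or
#' radical species and V3000 input are rejected.
#'
#' @param text Molfile contents as a single string or character vector of
#'   lines.
#' @return An `mcdl_graph`; the molecule name (header line 1) is attached as
#'   attribute `"name"`.
#' @export
read_molfile <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  if (length(lines) < 4L) stop("molfile too short", call. = FALSE)
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE)) {
    stop("V3000 molfiles are not supported", call. = FALSE)
  }
  natoms <- tryCatch(fixed_int(counts, 1L, 3L),
                     error = function(e) stop("malformed counts line (line 4)", call. = FALSE))
  nbonds <- tryCatch(fixed_int(counts, 4L, 6L),
                     error = function(e) stop("malformed counts line (line 4)", call. = FALSE))
  need <- 4L + natoms + nbonds
  if (length(lines) < need) {
    stop(sprintf("molfile truncated: expected %d atom and %d bond lines (line %d missing)",
                 natoms, nbonds, length(lines) + 1L), call. = FALSE)
  }
  el <- character(natoms); x <- y <- z <- numeric(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4L + i]
    if (nchar(ln) < 34L) stop(sprintf("malformed atom line %d", 4L + i), call. = FALSE)
    x[i] <- fixed_num(ln, 1L, 10L)
    y[i] <- fixed_num(ln, 11L, 20L)
    z[i] <- fixed_num(ln, 21L, 30L)
    el[i] <- trimws(substr(ln, 32L, 34L))
    chg <- if (nchar(ln) >= 39L) fixed_int(ln, 37L, 39L) else 0L
    if (chg != 0L) stop(sprintf("charged atom %d not supported", i), call. = FALSE)
  }
  begin <- end <- ord <- integer(nbonds); wedge <- character(nbonds)
  for (k in seq_len(nbonds)) {
    ln <- lines[4L + natoms + k]
    begin[k] <- fixed_int(ln, 1L, 3L)
    end[k] <- fixed_int(ln, 4L, 6L)
    ord[k] <- fixed_int(ln, 7L, 9L)
    st <- if (nchar(ln) >= 12L) fixed_int(ln, 10L, 12L) else 0L
    if (!ord[k] %in% 1:3) {
      stop(sprintf("unsupported bond order %d on bond line %d", ord[k], 4L + natoms + k),
           call. = FALSE)
    }
    wedge[k] <- switch(as.character(st), "0" = "none", "1" = "up", "6" = "down",
                       stop(sprintf("unsupported bond stereo code %d", st), call. = FALSE))
  }
  # property block: charges/isotopes/radicals rejected
  for (j in seq(4L + natoms + nbonds + 1L, length.out = max(0L, length(lines) - need))) {
    ln <- lines[j]
    if (grepl("^M  (CHG|ISO|RAD)", ln)) {
      stop("charged/isotopic/radical species are not supported: ", trimws(ln),
           call. = FALSE)
    }
    if (grepl("^M  END", ln)) break
  }
  dim3 <- any(abs(z) > 1e-4)
  if (!dim3) z[] <- 0
  if (dim3 && any(wedge != "none")) wedge[] <- "none"  # 3D input: wedges redundant
  g <- mcdl_graph(tibble::tibble(element = el, x = x, y = y, z = z,
                                 explicit_h = FALSE),
                  if (nbonds > 0L) tibble::tibble(begin = begin, end = end,
                                                  order = ord, wedge = wedge),
                  dimensionality = if (dim3) "3D" else "2D")
  attr(g, "name") <- trimws(lines[1L])
  g
}

#' Write an MDL MOLFILE (V2000)
#'
#' Byte-stable writer: the same graph always yields identical text.
#' Coordinates use the standard %10.4f fields; wedge flags are emitted as
#' bond stereo codes 1 (up) and 6 (down).
#'
#' @param g An `mcdl_graph`.
#' @param name Molecule name for the header line.
#' @return Molfile text (single string, newline-terminated blocks).
#' @export
write_molfile <- function(g, name = "") {
  validate_graph(g)
  a <- g$atoms; b <- g$bonds
  out <- c(name, "  mcdl", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  for (i in seq_len(nrow(a))) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          a$x[i], a$y[i], a$z[i], a$element[i]))
  }
  for (k in seq_len(nrow(b))) {
    st <- switch(b$wedge[k], none = 0L, up = 1L, down = 6L)
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0", b$begin[k], b$end[k],
                          b$order[k], st))
  }
  paste0(paste(c(out, "M  END"), collapse = "\n"), "\n")
}

#' Read an SDF batch file
#'
#' Splits on `$$$$` record delimiters and parses each record's molfile part
#' and `>  <tag>` property blocks. Per-record parse errors are reported with
#' the record index.
#'
#' @param text SDF contents as a single string or character vector of lines.
#' @return List of records, each a list with elements `graph` (an
#'   `mcdl_graph`), `name` (text) and `properties` (named character vector).
#' @export
read_sdf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  if (length(lines) == 0L || all(trimws(lines) == "")) return(list())
  delim <- which(trimws(lines) == "$$$$")
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  records <- list()
  for (r in seq_along(starts)) {
    if (starts[r] > ends[r]) next
    chunk <- lines[starts[r]:ends[r]]
    if (all(trimws(chunk) == "")) next
    mend <- which(grepl("^M  END", chunk))
    molpart <- if (length(mend) > 0L) chunk[1:mend[1L]] else chunk
    g <- tryCatch(read_molfile(molpart), error = function(e) {
      stop(sprintf("SDF record %d: %s", length(records) + 1L, conditionMessage(e)),
           call. = FALSE)
    })
    props <- character()
    rest <- if (length(mend) > 0L && mend[1L] < length(chunk)) {
      chunk[(mend[1L] + 1L):length(chunk)]
    } else character()
    j <- 1L
    while (j <= length(rest)) {
      ln <- rest[j]
      if (grepl("^>", ln)) {
        tag <- sub(".*<([^>]*)>.*", "\\1", ln)
        vals <- character()
        j <- j + 1L
        while (j <= length(rest) && trimws(rest[j]) != "") {
          vals <- c(vals, rest[j]); j <- j + 1L
        }
        if (tag %in% names(props)) {
          stop(sprintf("SDF record %d: duplicate property '%s'",
                       length(records) + 1L, tag), call. = FALSE)
        }
        props[tag] <- paste(vals, collapse = "\n")
      }
      j <- j + 1L
    }
    records[[length(records) + 1L]] <-
      list(graph = g, name = attr(g, "name"), properties = props)
  }
  records
}

#' Write an SDF batch file
#'
#' @param records List of records as returned by [read_sdf()], or a list of
#'   `mcdl_graph` objects.
#' @return SDF text with `$$$$` delimiters.
#' @export
write_sdf <- function(records) {
  chunks <- vapply(records, function(rec) {
    if (inherits(rec, "mcdl_graph")) rec <- list(graph = rec, name = attr(rec, "name"))
    txt <- write_molfile(rec$graph, if (is.null(rec$name)) "" else rec$name)
    props <- rec$properties
    if (!is.null(props) && length(props) > 0L) {
      for (tag in names(props)) {
        txt <- paste0(txt, sprintf(">  <%s>\n%s\n\n", tag, props[[tag]]))
      }
    }
    paste0(txt, "$$$$\n")
  }, character(1L))
  paste(chunks, collapse = "")
}
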