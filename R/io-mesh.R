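# Triangle-mesh I/O: PLY (ASCII and binary little-endian) and OBJ, plus the
# CSV side files (region mask, cohort metadata). Scalar fields are exported as
# a float vertex property named "quality"; colours as uchar red/green/blue.
# Face indices are 0-based on disk (PLY convention), 1-based in memory.

.ply_type_size <- function(type) {
  switch(type,
    char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
    float = 4L, float32 = 4L, double = 8L, float64 = 8L,
    stop("unsupported PLY property type '", type, "'", call. = FALSE)
  )
}

.ply_type_kind <- function(type) {
  if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
}

.ply_read_column <- function(raw, offset, size, type, n, stride) {
  pos <- rep(seq(0L, by = stride, length.out = n), each = size) +
    offset + seq_len(size)
  kind <- .ply_type_kind(type)
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  if (kind == "double") {
    readBin(raw[pos], what = "numeric", n = n, size = size, endian = "little")
  } else if (size == 4L && !signed) {
    # uint32 not directly supported by readBin; reinterpret
    v <- readBin(raw[pos], what = "integer", n = n, size = 4L,
                 endian = "little")
    ifelse(v < 0, v + 2^32, as.numeric(v))
  } else {
    readBin(raw[pos], what = "integer", n = n, size = size, signed = signed,
            endian = "little")
  }
}

#' Read a triangle mesh from PLY or OBJ
#'
#' Parses ASCII PLY, binary little-endian PLY, or Wavefront OBJ, requiring
#' triangular faces. If a `template` surface is supplied the result is
#' validated against it (vertex count and face array must match). Vertex order
#' is preserved exactly.
#'
#' @param path file path; format chosen by extension (`.ply`/`.obj`) or PLY
#'   magic.
#' @param template_id template identifier to stamp on the result.
#' @param template optional `corr_surface` to validate correspondence against.
#' @return a `corr_surface`; any `quality` scalar property is attached as
#'   attribute `"quality"`.
#' @export
read_surface <- function(path, template_id = "template", template = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  mesh <- if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    .read_obj(path)
  } else if (identical(first, "ply") || grepl("\\.ply$", path,
                                              ignore.case = TRUE)) {
    .read_ply(path)
  } else {
    stop("unrecognised mesh format for ", path, call. = FALSE)
  }
  surf <- corr_surface(mesh$vertices, mesh$faces, template_id)
  if (!is.null(mesh$quality)) attr(surf, "quality") <- mesh$quality
  if (!is.null(template)) {
    if (nrow(surf$vertices) != nrow(template$vertices)) {
      stop(sprintf(paste0("correspondence error: file has %d vertices but ",
                          "template '%s' has %d"),
                   nrow(surf$vertices), template_id, nrow(template$vertices)),
           call. = FALSE)
    }
    if (!identical(surf$faces, template$faces)) {
      stop("correspondence error: face array differs from template",
           call. = FALSE)
    }
  }
  surf
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(header) == 0L && (length(line) == 0L || line != "ply")) {
      stop("malformed PLY ", path, ": line 1: missing 'ply' magic",
           call. = FALSE)
    }
    if (length(line) == 0L) {
      stop("malformed PLY ", path, ": header line ", length(header) + 1,
           ": unexpected end of file", call. = FALSE)
    }
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 1000L) {
      stop("malformed PLY ", path, ": no end_header within 1000 lines",
           call. = FALSE)
    }
  }
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) {
    stop("malformed PLY ", path, ": missing format line", call. = FALSE)
  }
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format '", fmt, "' in ", path, call. = FALSE)
  }

  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (i in seq_along(header)) {
    tok <- strsplit(header[i], "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) {
        stop("malformed PLY ", path, ": header line ", i,
             ": property before element", call. = FALSE)
      }
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                    index_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  ve <- elements[["vertex"]]
  fe <- elements[["face"]]
  if (is.null(ve) || is.null(fe)) {
    stop("malformed PLY ", path, ": need vertex and face elements",
         call. = FALSE)
  }
  vprops <- ve$props
  if (!all(c("x", "y", "z") %in% names(vprops))) {
    stop("malformed PLY ", path, ": vertex element lacks x/y/z",
         call. = FALSE)
  }
  fprop <- fe$props[[1]]
  if (!isTRUE(fprop$list)) {
    stop("malformed PLY ", path, ": face element lacks a list property",
         call. = FALSE)
  }

  if (fmt == "ascii") {
    toks <- scan(con, what = numeric(), quiet = TRUE)
    np <- length(vprops)
    nv <- ve$count
    need <- nv * np
    if (length(toks) < need) {
      stop("malformed PLY ", path, ": truncated vertex data", call. = FALSE)
    }
    vmat <- matrix(toks[seq_len(need)], nrow = nv, ncol = np, byrow = TRUE)
    colnames(vmat) <- names(vprops)
    ftoks <- toks[-seq_len(need)]
    nf <- fe$count
    if (length(ftoks) == nf * 4L &&
        all(ftoks[seq(1L, by = 4L, length.out = nf)] == 3)) {
      fidx <- matrix(ftoks, nrow = nf, ncol = 4L, byrow = TRUE)[, 2:4]
    } else {
      # irregular counts: walk to locate the non-triangular face
      i <- 1L
      for (k in seq_len(nf)) {
        cnt <- ftoks[i]
        if (is.na(cnt)) {
          stop("malformed PLY ", path, ": truncated face data at face ", k,
               call. = FALSE)
        }
        if (cnt != 3) {
          stop(sprintf("non-triangular face in %s: face %d has %d vertices",
                       path, k, cnt), call. = FALSE)
        }
        i <- i + 1L + cnt
      }
      stop("malformed PLY ", path, ": face data length mismatch",
           call. = FALSE)
    }
  } else {
    sizes <- vapply(vprops, function(p) .ply_type_size(p$type), integer(1))
    stride <- sum(sizes)
    offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
    nv <- ve$count
    raw <- readBin(con, "raw", n = nv * stride)
    if (length(raw) < nv * stride) {
      stop("malformed PLY ", path, ": truncated binary vertex data",
           call. = FALSE)
    }
    vmat <- matrix(0, nv, length(vprops),
                   dimnames = list(NULL, names(vprops)))
    for (j in seq_along(vprops)) {
      vmat[, j] <- .ply_read_column(raw, offsets[j], sizes[j],
                                    vprops[[j]]$type, nv, stride)
    }
    nf <- fe$count
    cs <- .ply_type_size(fprop$count_type)
    is <- .ply_type_size(fprop$index_type)
    fraw <- readBin(con, "raw", n = nf * (cs + 3L * is) + 1L)
    fstride <- cs + 3L * is
    if (length(fraw) != nf * fstride) {
      stop("malformed PLY ", path,
           ": face block size implies non-triangular faces", call. = FALSE)
    }
    counts <- .ply_read_column(fraw, 0L, cs, fprop$count_type, nf, fstride)
    if (any(counts != 3)) {
      k <- which(counts != 3)[1]
      stop(sprintf("non-triangular face in %s: face %d has %d vertices",
                   path, k, counts[k]), call. = FALSE)
    }
    fidx <- matrix(0L, nf, 3L)
    for (j in 1:3) {
      fidx[, j] <- .ply_read_column(fraw, cs + (j - 1L) * is, is,
                                    fprop$index_type, nf, fstride)
    }
  }
  out <- list(vertices = vmat[, c("x", "y", "z"), drop = FALSE],
              faces = matrix(as.integer(fidx), ncol = 3L) + 1L)
  if ("quality" %in% colnames(vmat)) out$quality <- vmat[, "quality"]
  out
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) {
    stop("malformed OBJ ", path, ": no vertices", call. = FALSE)
  }
  vmat <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(t) {
    as.numeric(t[2:4])
  }))
  fidx <- lapply(seq_along(flines), function(k) {
    t <- strsplit(trimws(flines[k]), "\\s+")[[1]][-1]
    if (length(t) != 3L) {
      stop(sprintf("non-triangular face in %s: face %d has %d vertices",
                   path, k, length(t)), call. = FALSE)
    }
    as.integer(vapply(strsplit(t, "/"), `[[`, character(1), 1L))
  })
  list(vertices = vmat, faces = do.call(rbind, fidx))
}

#' Write a triangle mesh as PLY
#'
#' Optionally attaches a per-vertex scalar field (float property `quality`)
#' and per-vertex colours (uchar `red`/`green`/`blue`). Coordinates are
#' written as doubles so a round trip preserves them to well below 1e-6 mm.
#'
#' @param surface a `corr_surface`.
#' @param path output path.
#' @param scalars optional length-N numeric written as `quality`.
#' @param colors optional N x 3 integer matrix (0-255) written as uchar RGB.
#' @param binary write `binary_little_endian` (default) or ASCII.
#' @return invisibly `path`.
#' @export
write_surface <- function(surface, path, scalars = NULL, colors = NULL,
                          binary = TRUE) {
  v <- surface$vertices
  f <- surface$faces - 1L
  n <- nrow(v)
  if (!is.null(scalars) && length(scalars) != n) {
    stop("scalars must have one value per vertex", call. = FALSE)
  }
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "integer"
    stopifnot(nrow(colors) == n, ncol(colors) == 3L,
              all(colors >= 0L & colors <= 255L))
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment growthmorph corresponded surface",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  if (!is.null(scalars)) hdr <- c(hdr, "property float quality")
  if (!is.null(colors)) {
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    stride <- 24L + (!is.null(scalars)) * 4L + (!is.null(colors)) * 3L
    out <- raw(n * stride)
    base <- stride * (seq_len(n) - 1L)
    out[rep(base, each = 24L) + rep(1:24, n)] <-
      writeBin(as.numeric(t(v)), raw(), size = 8L, endian = "little")
    off <- 24L
    if (!is.null(scalars)) {
      out[rep(base, each = 4L) + off + rep(1:4, n)] <-
        writeBin(as.numeric(scalars), raw(), size = 4L, endian = "little")
      off <- off + 4L
    }
    if (!is.null(colors)) {
      out[rep(base, each = 3L) + off + rep(1:3, n)] <- as.raw(t(colors))
    }
    writeBin(out, con)
    nf <- nrow(f)
    fout <- raw(nf * 13L)                       # uchar count + 3 x int32
    fbase <- 13L * (seq_len(nf) - 1L)
    fout[fbase + 1L] <- as.raw(3L)
    fout[rep(fbase, each = 12L) + 1L + rep(1:12, nf)] <-
      writeBin(as.integer(t(f)), raw(), size = 4L, endian = "little")
    writeBin(fout, con)
  } else {
    vtxt <- sprintf("%.9f %.9f %.9f", v[, 1], v[, 2], v[, 3])
    if (!is.null(scalars)) vtxt <- paste(vtxt, sprintf("%.6g", scalars))
    if (!is.null(colors)) {
      vtxt <- paste(vtxt, colors[, 1], colors[, 2], colors[, 3])
    }
    writeLines(vtxt, con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Write a triangle mesh as Wavefront OBJ
#' @inheritParams write_surface
#' @return invisibly `path`.
#' @export
write_obj <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  writeLines(c(sprintf("v %.9f %.9f %.9f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}

#' Read / write a region mask CSV
#'
#' The on-disk format has columns `vertex_index` (0-based, matching PLY
#' indexing) and `label`.
#'
#' @param path CSV path.
#' @param n_template optional expected template vertex count.
#' @return `read_region_mask`: a `region_mask`.
#' @export
read_region_mask <- function(path, n_template = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("vertex_index", "label") %in% names(df)))
  labels <- character(nrow(df))
  labels[df$vertex_index + 1L] <- df$label
  region_mask(labels, n_template)
}

#' @rdname read_region_mask
#' @param mask a `region_mask` to write.
#' @export
write_region_mask <- function(mask, path) {
  utils::write.csv(
    data.frame(vertex_index = seq_along(mask$labels) - 1L,
               label = as.character(mask$labels)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Diverging red-white-blue vertex colours for a signed field
#'
#' Red encodes outward (positive) change, white zero, blue inward (negative),
#' saturating at `limit` mm.
#'
#' @param values signed per-vertex scalars (mm).
#' @param limit saturation magnitude (mm); defaults to `max(abs(values))`.
#' @return N x 3 integer matrix of 0-255 RGB values.
#' @export
colormap_diverging <- function(values, limit = NULL) {
  if (is.null(limit)) limit <- max(abs(values), 1e-12)
  t <- pmax(pmin(values / limit, 1), -1)
  up <- pmax(t, 0)
  dn <- pmax(-t, 0)
  cbind(red = as.integer(round(255 * (1 - dn))),
        green = as.integer(round(255 * (1 - pmax(up, dn)))),
        blue = as.integer(round(255 * (1 - up))))
}

#' Bicolour significance vertex colours
#'
#' Yellow where the pointwise test is significant (p below alpha), green
#' elsewhere.
#'
#' @param significant logical per-vertex significance flags.
#' @return N x 3 integer matrix of 0-255 RGB values.
#' @export
colormap_significance <- function(significant) {
  cbind(red = ifelse(significant, 255L, 0L),
        green = 255L,
        blue = 0L)
}
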