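# Minimal NRRD volumetric map I/O (ASCII encoding), enough to exchange
# absorbed-energy and fluence maps with standard viewers.

#' Write a 3-D map as an ASCII-encoded NRRD file
#'
#' Axis order is x-fastest (matching R array storage, 0-based voxel
#' indexing); spacing is the voxel size on all axes.
#'
#' @param x 3-D numeric array.
#' @param path Output path (conventionally `.nrrd`).
#' @param voxel_size Voxel edge, mm.
#' @return The path, invisibly.
#' @export
write_nrrd <- function(x, path, voxel_size = 1) {
  d <- dim(x)
  if (length(d) != 3) stop("x must be a 3-D array")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %g %g %g", voxel_size, voxel_size, voxel_size),
    "encoding: ascii",
    ""), con)
  writeLines(paste(format(as.vector(x), digits = 9, trim = TRUE,
                          scientific = TRUE),
                   collapse = " "), con)
  invisible(path)
}

#' Read an ASCII-encoded NRRD file written by [write_nrrd()]
#'
#' @param path File path.
#' @return A 3-D array with attribute `voxel_size`.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("not a NRRD file")
  blank <- which(lines == "")[1]
  hdr <- lines[2:(blank - 1)]
  get <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  if (!identical(get("encoding"), "ascii")) stop("only ascii encoding supported")
  sizes <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("spacings"), "\\s+")[[1]])[1]
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != prod(sizes)) stop("NRRD payload size mismatch")
  out <- array(vals, dim = sizes)
  attr(out, "voxel_size") <- sp
  out
}
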