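# Plain-text network checkpoints. Weights are stored per tensor as
# int16-quantized values with one scale factor each (quantization error
# ~3e-5 of the tensor range, far below optimizer noise), so trained
# localizers ship as small, diff-able text files.

flatten_params <- function(params, path = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (is.list(p)) {
      if (!is.null(p$type)) {
        for (lf in intersect(names(p), c("W", "b", "gamma", "beta")))
          out[[paste0(key, ".", lf)]] <- p[[lf]]
      } else {
        out <- c(out, flatten_params(p, key))
      }
    }
  }
  out
}

#' Save a localizer as a plain-text checkpoint
#'
#' @param net An `ulm_net` or `supbd_fit`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
save_supbd_checkpoint <- function(net, path) {
  if (inherits(net, "supbd_fit")) net <- net$net
  con <- file(path, "w")
  on.exit(close(con))
  sp <- net$spec
  writeLines(sprintf(
    "# ulmkit localizer checkpoint v1\nspec %d %d %d %d %d %d %d %g",
    sp$channels, sp$n_res, sp$k_first, sp$k_inner, sp$k_last,
    sp$upscale, as.integer(sp$squash), sp$leaky), con)
  fl <- flatten_params(net$params)
  for (nm in names(fl)) {
    v <- as.numeric(fl[[nm]])
    scale <- max(abs(v), 1e-12) / 32767
    q <- as.integer(round(v / scale))
    writeLines(sprintf("tensor %s %d %.8e", nm, length(v), scale), con)
    writeLines(paste(q, collapse = " "), con)
  }
  invisible(path)
}

#' Load a localizer from a plain-text checkpoint
#'
#' @param path Checkpoint file written by [save_supbd_checkpoint()].
#' @return An `ulm_net`.
#' @export
load_supbd_checkpoint <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  sp_f <- strsplit(lines[1], " ")[[1]]
  stopifnot(sp_f[1] == "spec")
  v <- as.numeric(sp_f[-1])
  spec <- supbd_spec(channels = v[1], n_res = v[2], k_first = v[3],
                     k_inner = v[4], k_last = v[5], upscale = v[6],
                     squash = v[7] == 1, leaky = v[8])
  net <- build_supbd(spec, seed = 0L)
  i <- 2L
  vals <- list()
  while (i <= length(lines)) {
    hd <- strsplit(lines[i], " ")[[1]]
    stopifnot(hd[1] == "tensor")
    n <- as.integer(hd[3]); scale <- as.numeric(hd[4])
    q <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
    stopifnot(length(q) == n)
    vals[[hd[2]]] <- q * scale
    i <- i + 2L
  }
  assign_leaf <- function(params, keys, value) {
    k <- keys[1]
    if (length(keys) == 1L) {
      old <- params[[k]]
      stopifnot(length(old) == length(value))
      params[[k]][] <- value
    } else {
      params[[k]] <- assign_leaf(params[[k]], keys[-1], value)
    }
    params
  }
  for (nm in names(vals))
    net$params <- assign_leaf(net$params, strsplit(nm, ".",
                                                   fixed = TRUE)[[1]],
                              vals[[nm]])
  net
}
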