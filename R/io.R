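#' Save and load memory state
#'
#' AMR state is serialized as a JSON header (label, dimensions, format
#' version) next to the raw `n_levels x n_args` integer weight matrix in
#' CSV; round-trips are bit-exact. A whole memory system is a directory of
#' per-register pairs plus a quantizer file and a manifest.
#'
#' @param amr a [weighted_amr()].
#' @param prefix file path prefix; `<prefix>.json` and `<prefix>.csv` are
#'   written.
#' @return `amr_save()` returns `prefix` invisibly; `amr_load()` the
#'   reconstructed register.
#' @export
amr_save <- function(amr, prefix) {
  hdr <- list(format = "weam-amr-1", label = amr$label,
              n_args = amr_n_args(amr), n_levels = amr_n_levels(amr))
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE)
  utils::write.table(amr$weights, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname amr_save
#' @export
amr_load <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(hdr$format, "weam-amr-1"))
    stop_weam("unsupported register format: ", hdr$format)
  w <- as.matrix(utils::read.csv(paste0(prefix, ".csv"), header = FALSE))
  storage.mode(w) <- "integer"
  dimnames(w) <- NULL
  amr <- weighted_amr(hdr$n_args, hdr$n_levels, hdr$label)
  if (!all(dim(w) == dim(amr$weights)))
    stop_weam("weight matrix does not match the header dimensions")
  amr$weights <- w
  amr
}

#' @rdname amr_save
#' @param q a [quantizer_fit()] object.
#' @param path JSON file path.
#' @export
quantizer_save <- function(q, path) {
  jsonlite::write_json(list(format = "weam-quantizer-1",
                            n_dims = q$n_dims, n_levels = q$n_levels,
                            lo = q$lo, hi = q$hi),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname amr_save
#' @export
quantizer_load <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(d$format, "weam-quantizer-1"))
    stop_weam("unsupported quantizer format: ", d$format)
  structure(list(n_dims = d$n_dims, n_levels = d$n_levels,
                 lo = as.numeric(d$lo), hi = as.numeric(d$hi)),
            class = "quantizer")
}

#' @rdname amr_save
#' @param sys a [memory_system()].
#' @param dir directory to write (created if needed).
#' @export
ms_save <- function(sys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(sys$registers)
  files <- sprintf("reg_%03d", seq_along(labels))
  manifest <- list(format = "weam-system-1",
                   labels = labels, files = files,
                   n_args = sys$n_args, n_levels = sys$n_levels,
                   params = unclass(sys$params),
                   has_quantizer = !is.null(sys$quantizer))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(labels))
    amr_save(sys$registers[[k]], file.path(dir, files[k]))
  if (!is.null(sys$quantizer))
    quantizer_save(sys$quantizer, file.path(dir, "quantizer.json"))
  invisible(dir)
}

#' @rdname amr_save
#' @export
ms_load <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "weam-system-1"))
    stop_weam("unsupported system format: ", man$format)
  p <- man$params
  params <- recognition_params(p$iota, p$kappa, p$xi, p$sigma,
                               p$sigma_units %||% "rows")
  q <- if (isTRUE(man$has_quantizer))
    quantizer_load(file.path(dir, "quantizer.json"))
  sys <- memory_system(man$labels, man$n_args, man$n_levels, q, params)
  for (k in seq_along(man$labels))
    sys$registers[[man$labels[k]]] <- amr_load(file.path(dir, man$files[k]))
  sys
}

#' The packaged worked-example strings
#'
#' The phonetic transcription of one recognized utterance together with the
#' raw and bigram-simplified output strings of the memory and of the bare
#' network, shipped as a plain-text fixture. Tokenizing them with
#' [phone_tokenize()] gives lengths 27, 225, 178, 41 and 37, and the token
#' Levenshtein distances reproduce the reference worked example.
#'
#' @return named list of character scalars: `transcription`, `network`,
#'   `memory`, `simplified_network`, `simplified_memory`, `orthographic`.
#' @export
table5_strings <- function() {
  path <- system.file("extdata", "table5.json", package = "weam",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Recompute the worked-example distance table
#'
#' Tokenizes the packaged strings and recomputes every printed length and
#' token Levenshtein distance.
#'
#' @return data.frame with columns `quantity` and `value`.
#' @export
table5_distances <- function() {
  s <- table5_strings()
  tk <- lapply(s[c("transcription", "network", "memory",
                   "simplified_network", "simplified_memory")],
               phone_tokenize)
  data.frame(
    quantity = c("len_transcription", "len_network", "len_memory",
                 "len_simplified_network", "len_simplified_memory",
                 "Net2Utt", "Mem2Utt", "Net2Mem",
                 "SNet2Utt", "SMem2Utt", "SNet2SMem"),
    value = c(lengths(tk)[1:5],
              phone_levenshtein(tk$network, tk$transcription),
              phone_levenshtein(tk$memory, tk$transcription),
              phone_levenshtein(tk$network, tk$memory),
              phone_levenshtein(tk$simplified_network, tk$transcription),
              phone_levenshtein(tk$simplified_memory, tk$transcription),
              phone_levenshtein(tk$simplified_network, tk$simplified_memory)),
    row.names = NULL)
}
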