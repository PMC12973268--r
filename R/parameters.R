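# Parameter model: a flat TOML-like key-value schema with one [element.X]
# block per element plus a [global] block.  All validation lives here, so the
# rest of the package can assume a complete, coherent parameter set.

.parse_kv_value <- function(txt, key, path) {
  parts <- trimws(strsplit(txt, ",")[[1]])
  if (any(parts == "")) stop(sprintf("parse error in '%s': empty entry for key '%s'", path, key))
  num <- suppressWarnings(as.numeric(parts))
  if (all(!is.na(num))) num else parts
}

#' Load a tight-binding parameter set
#'
#' Reads the flat key-value parameter schema shipped with the package (a
#' transcription of the published GFN2 element tables, extended with atomic
#' spin constants `W` and shell-resolved Hubbard `U` values).  Missing `U`
#' entries default to 0 for every shell, missing `W` entries to 0, and a
#' missing scaling factor `alpha` defaults to 0.5.
#'
#' @param path Path to a parameter file.  The default is the parametrization
#'   shipped in `inst/extdata/gfn2_elements.toml`.
#' @return An object of class `tb_parameters`: a list with components
#'   `global` (named list of scalars/vectors) and `elements` (named list per
#'   element with shell-resolved vectors, the symmetric spin-constant matrix
#'   `W` and the Hubbard vector `U`).
#' @export
load_parameters <- function(path = default_parameter_file()) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  section <- NULL
  raw <- list(global = list(), elements = list())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      if (!grepl("^\\[[A-Za-z0-9._]+\\]$", ln))
        stop("parse error: malformed section header '", ln, "'")
      section <- gsub("^\\[|\\]$", "", ln)
      if (grepl("^element\\.", section)) {
        el <- sub("^element\\.", "", section)
        raw$elements[[el]] <- list()
      } else if (section != "global") {
        stop("parse error: unknown section '", section, "'")
      }
      next
    }
    if (!grepl("=", ln)) stop("parse error: expected 'key = value', got '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- .parse_kv_value(sub("^[^=]*=", "", ln), key, path)
    if (is.null(section)) stop("parse error: key '", key, "' outside any section")
    if (section == "global") raw$global[[key]] <- val
    else raw$elements[[sub("^element\\.", "", section)]][[key]] <- val
  }
  .validate_parameters(raw, path)
}

#' @rdname load_parameters
#' @export
default_parameter_file <- function() {
  system.file("extdata", "gfn2_elements.toml", package = "xtbu", mustWork = TRUE)
}

.shell_l <- function(shell_labels) {
  l <- match(substr(shell_labels, 2, 2), c("s", "p", "d")) - 1L
  if (anyNA(l)) stop("validation error: unknown shell label among: ",
                     paste(shell_labels, collapse = ", "))
  l
}

.validate_parameters <- function(raw, path = "<memory>") {
  g <- raw$global
  g_defaults <- list(ks = 1.85, kp = 2.23, kd = 2.23, ken = -0.02, wexp = 0.5,
                     rep_kexp = 1.5, rep_kexp_light = 1.0, gexp = 2.0,
                     gam3_shell = c(1.0, 0.5, 0.25), dmp3 = 3.0, dmp5 = 4.0,
                     mp_kexp = 4.0, mp_shift = 1.2, mp_rmax = 5.0,
                     cn_ka = 10.0, cn_kb = 20.0, cn_rshift = 2.0, alpha = 0.5)
  for (k in names(g_defaults)) if (is.null(g[[k]])) g[[k]] <- g_defaults[[k]]
  if (g$alpha < 0 || g$alpha > 1)
    stop("validation error: global key 'alpha' must lie in [0, 1]")

  req <- c("shells", "ngauss", "levels", "slater", "refocc", "kcn", "shpoly",
           "gam", "lgam", "gam3", "arep", "zeff", "en", "rcov")
  elements <- list()
  for (el in names(raw$elements)) {
    e <- raw$elements[[el]]
    for (k in req) if (is.null(e[[k]]))
      stop(sprintf("validation error: element block '%s' is missing key '%s'", el, k))
    shells <- as.character(e$shells)
    nsh <- length(shells)
    n_pqn <- as.integer(substr(shells, 1, 1))
    l <- .shell_l(shells)
    per_shell <- c("ngauss", "levels", "slater", "refocc", "kcn", "shpoly", "lgam")
    for (k in per_shell) if (length(e[[k]]) != nsh)
      stop(sprintf("validation error: element '%s', key '%s' must have %d entries", el, k, nsh))
    if (any(e$slater <= 0))
      stop("validation error: element '", el, "': Slater exponents must be positive")
    nw <- nsh * (nsh + 1) / 2
    W <- matrix(0, nsh, nsh)
    if (!is.null(e$W)) {
      if (length(e$W) != nw)
        stop(sprintf("validation error: element '%s', key 'W' must have %d entries (lower triangle)", el, nw))
      W[upper.tri(W, diag = TRUE)] <- 0
      idx <- 1L
      for (i in seq_len(nsh)) for (j in i:nsh) { W[i, j] <- W[j, i] <- e$W[idx]; idx <- idx + 1L }
    }
    U <- if (is.null(e$U)) rep(0, nsh) else as.numeric(e$U)
    if (length(U) != nsh)
      stop(sprintf("validation error: element '%s', key 'U' must have %d entries", el, nsh))
    if (any(U < 0)) stop("validation error: element '", el, "': U values must be >= 0")
    elements[[el]] <- list(
      shells = shells, n = n_pqn, l = l, ngauss = as.integer(e$ngauss),
      levels = as.numeric(e$levels), slater = as.numeric(e$slater),
      refocc = as.numeric(e$refocc), kcn = as.numeric(e$kcn),
      shpoly = as.numeric(e$shpoly), gam = as.numeric(e$gam[1]),
      lgam = as.numeric(e$lgam), gam3 = as.numeric(e$gam3[1]),
      arep = as.numeric(e$arep[1]), zeff = as.numeric(e$zeff[1]),
      en = as.numeric(e$en[1]), rcov = as.numeric(e$rcov[1]),
      dkernel = as.numeric((e$dkernel %||% 0)[1]),
      qkernel = as.numeric((e$qkernel %||% 0)[1]),
      mprad = as.numeric((e$mprad %||% 2.5)[1]),
      mpvcn = as.numeric((e$mpvcn %||% 1)[1]),
      W = W, U = U)
  }
  structure(list(global = g, elements = elements), class = "tb_parameters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter set back to its file schema
#'
#' Inverse of [load_parameters()]; `write_parameters()` followed by
#' [load_parameters()] reproduces the parameter set exactly (round trip).
#'
#' @param params A `tb_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "tb_parameters"))
  fmt <- function(x) paste(vapply(x, function(v)
    if (is.numeric(v)) sprintf("%.12g", v) else as.character(v), ""), collapse = ", ")
  out <- c("[global]")
  for (k in names(params$global)) out <- c(out, sprintf("%s = %s", k, fmt(params$global[[k]])))
  for (el in names(params$elements)) {
    e <- params$elements[[el]]
    out <- c(out, "", sprintf("[element.%s]", el),
             sprintf("shells = %s", fmt(e$shells)),
             sprintf("ngauss = %s", fmt(e$ngauss)),
             sprintf("levels = %s", fmt(e$levels)),
             sprintf("slater = %s", fmt(e$slater)),
             sprintf("refocc = %s", fmt(e$refocc)),
             sprintf("kcn = %s", fmt(e$kcn)),
             sprintf("shpoly = %s", fmt(e$shpoly)),
             sprintf("gam = %s", fmt(e$gam)),
             sprintf("lgam = %s", fmt(e$lgam)),
             sprintf("gam3 = %s", fmt(e$gam3)),
             sprintf("arep = %s", fmt(e$arep)),
             sprintf("zeff = %s", fmt(e$zeff)),
             sprintf("en = %s", fmt(e$en)),
             sprintf("rcov = %s", fmt(e$rcov)),
             sprintf("dkernel = %s", fmt(e$dkernel)),
             sprintf("qkernel = %s", fmt(e$qkernel)),
             sprintf("mprad = %s", fmt(e$mprad)),
             sprintf("mpvcn = %s", fmt(e$mpvcn)),
             sprintf("W = %s", fmt(unlist(lapply(seq_along(e$shells), function(i)
               e$W[i, i:length(e$shells)])))),
             sprintf("U = %s", fmt(e$U)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Override spin constants or Hubbard U values in a parameter set
#'
#' Convenience used by the optimization layer: set named entries such as
#' `Wdd`, `Wss`, `Wsp` (symmetric) or `Ud`, `Us`, `Up` for one element.
#'
#' @param params A `tb_parameters` object.
#' @param element Element symbol the overrides apply to.
#' @param values Named numeric vector, names like `"Wdd"`, `"Ud"`.
#' @return The modified `tb_parameters` object.
#' @export
set_parameters <- function(params, element, values) {
  stopifnot(inherits(params, "tb_parameters"))
  e <- params$elements[[element]]
  if (is.null(e)) stop("unsupported element: ", element)
  lmap <- c(s = 0L, p = 1L, d = 2L)
  for (nm in names(values)) {
    if (grepl("^W[spd][spd]$", nm)) {
      i <- match(lmap[[substr(nm, 2, 2)]], e$l)
      j <- match(lmap[[substr(nm, 3, 3)]], e$l)
      if (is.na(i) || is.na(j)) stop("element ", element, " has no shell pair for ", nm)
      e$W[i, j] <- e$W[j, i] <- values[[nm]]
    } else if (grepl("^U[spd]$", nm)) {
      i <- match(lmap[[substr(nm, 2, 2)]], e$l)
      if (is.na(i)) stop("element ", element, " has no shell for ", nm)
      if (values[[nm]] < 0) stop("validation error: U values must be >= 0")
      e$U[i] <- values[[nm]]
    } else stop("unknown parameter name: ", nm)
  }
  params$elements[[element]] <- e
  params
}
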