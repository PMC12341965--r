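#' Read a signed, directed interaction network (SIF)
#'
#' Tab-separated Cytoscape-style dialect with the relation in the second
#' column: `source<TAB>relation<TAB>target`. Accepted relation tokens
#' (case-insensitive): `->`, `activate`, `activates` for activation and
#' `-|`, `inhibit`, `inhibits` for inhibition. Lines starting with `#` and
#' blank lines are skipped. Duplicate (source, target, sign) triples are
#' dropped with a message; malformed rows are rejected, never repaired.
#'
#' @param path SIF file.
#' @param auto_self_regulate see [pkn()]; by default a node without any
#'   regulator is a hard error because the modeling pipeline requires a
#'   self-contained topology.
#' @return a [pkn()]. Node order is first appearance in the file.
#' @export
read_sif <- function(path, auto_self_regulate = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) stop("empty SIF file: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3)) {
    stop("SIF line ", keep[which(nf != 3)[1]],
         ": expected 3 tab-separated fields, got ", nf[which(nf != 3)[1]])
  }
  m <- do.call(rbind, fields)
  rel <- tolower(trimws(m[, 2]))
  sign <- ifelse(rel %in% c("->", "activate", "activates"), 1L,
                 ifelse(rel %in% c("-|", "inhibit", "inhibits"), -1L, NA_integer_))
  if (anyNA(sign)) {
    i <- which(is.na(sign))[1]
    stop("SIF line ", keep[i], ": unknown relation token '", m[i, 2], "'")
  }
  ints <- data.frame(source = trimws(m[, 1]), target = trimws(m[, 3]),
                     sign = sign, stringsAsFactors = FALSE)
  pkn(ints, auto_self_regulate = auto_self_regulate)
}

#' Write a network as SIF
#' @param network a [pkn()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  rel <- ifelse(network$interactions$sign == 1L, "->", "-|")
  writeLines(paste(network$interactions$source, rel,
                   network$interactions$target, sep = "\t"), path)
  invisible(path)
}

#' Read a steady-state calibration profile
#'
#' One `node<TAB>value` pair per line with value `0`, `1` or `-` (dash =
#' explicitly unspecified). Nodes not listed are implicitly unspecified.
#'
#' @param path tab-delimited file.
#' @param network optional [pkn()] used to validate node names.
#' @return a [calibration_profile()].
#' @export
read_calibration <- function(path, network = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    stop("calibration line ", keep[which(nf != 2)[1]],
         ": expected 'node<TAB>value'")
  }
  m <- do.call(rbind, fields)
  vals <- trimws(m[, 2])
  bad <- !vals %in% c("0", "1", "-")
  if (any(bad)) {
    stop("calibration line ", keep[which(bad)[1]], ": value '",
         vals[which(bad)[1]], "' outside {0, 1, -}")
  }
  x <- setNames(rep(NA_integer_, length(vals)), trimws(m[, 1]))
  x[vals != "-"] <- as.integer(vals[vals != "-"])
  calibration_profile(x, network = network)
}

#' Write a calibration profile
#' @param profile a [calibration_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(profile, path) {
  vals <- ifelse(is.na(profile), "-", as.character(profile))
  writeLines(paste(names(profile), vals, sep = "\t"), path)
  invisible(path)
}

#' Read a drug panel
#'
#' Grammar: `drug<TAB>effect<TAB>target1<TAB>target2...` with effect
#' `inhibits` (clamp targets to 0) or `activates` (clamp to 1).
#'
#' @param path tab-delimited file.
#' @param network optional [pkn()] to validate target nodes.
#' @return a [drug_panel()].
#' @export
read_drug_panel <- function(path, network = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  entries <- list()
  for (i in keep) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3) {
      stop("drug panel line ", i, ": expected 'drug<TAB>effect<TAB>target...'")
    }
    if (!f[2] %in% c("inhibits", "activates")) {
      stop("drug panel line ", i, ": effect '", f[2],
           "' must be 'inhibits' or 'activates'")
    }
    entries[[f[1]]] <- list(effect = f[2], targets = f[-(1:2)])
  }
  panel <- drug_panel(entries)
  if (!is.null(network)) {
    targets <- unique(unlist(lapply(panel$entries, `[[`, "targets")))
    unknown <- setdiff(targets, network$nodes)
    if (length(unknown) > 0) {
      stop("drug panel targets node(s) not in the network: ",
           paste(unknown, collapse = ", "))
    }
  }
  panel
}

#' Write a drug panel
#' @param panel a [drug_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_drug_panel <- function(panel, path) {
  lines <- vapply(names(panel$entries), function(d) {
    e <- panel$entries[[d]]
    paste(c(d, e$effect, e$targets), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a perturbation list
#'
#' One perturbation per line: a single drug name, or two tab-separated drug
#' names for a pair.
#'
#' @param path file.
#' @param panel optional [drug_panel()] to validate drug names.
#' @return list of character vectors (length 1 or 2).
#' @export
read_perturbations <- function(path, panel = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  perts <- lapply(strsplit(lines[keep], "\t", fixed = TRUE), trimws)
  for (i in seq_along(perts)) {
    p <- perts[[i]]
    if (!length(p) %in% 1:2 || anyDuplicated(p)) {
      stop("perturbation line ", keep[i],
           ": expected one drug or two distinct drugs")
    }
    if (!is.null(panel)) {
      unknown <- setdiff(p, names(panel$entries))
      if (length(unknown) > 0) {
        stop("perturbation line ", keep[i], ": unknown drug(s): ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  perts
}

#' Write a perturbation list
#' @param perturbations list of character vectors (length 1 or 2).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_perturbations <- function(perturbations, path) {
  writeLines(vapply(perturbations, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Read output-node weights
#'
#' Grammar: `node<TAB>weight` with a signed real weight per output node.
#'
#' @param path file.
#' @param network optional [pkn()] to validate node names.
#' @return an [output_spec()].
#' @export
read_output_spec <- function(path, network = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    stop("model-outputs file: expected 'node<TAB>weight' per line")
  }
  m <- do.call(rbind, fields)
  w <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(w)) stop("model-outputs file: non-numeric weight")
  spec <- output_spec(setNames(w, trimws(m[, 1])))
  if (!is.null(network)) {
    unknown <- setdiff(names(spec$weights), network$nodes)
    if (length(unknown) > 0) {
      stop("output spec names node(s) not in the network: ",
           paste(unknown, collapse = ", "))
    }
  }
  spec
}

#' Write output-node weights
#' @param outputs an [output_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_output_spec <- function(outputs, path) {
  writeLines(paste(names(outputs$weights), outputs$weights, sep = "\t"), path)
  invisible(path)
}

#' Write a Boolean model as equation text (.bnm)
#'
#' Dialect: one equation per line, e.g.
#' `B *= ((A) or (C)) and not ((D))`; equations without a link operator are
#' `B *= ((A))` or `B *= not ((D))`. Header comment lines carry attached
#' metadata (`# fitness: <float>`, `# seed: <int>`).
#'
#' @param model a `boolean_model`.
#' @param path output file.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, seed = NULL) {
  header <- character()
  if (!is.na(model$fitness)) {
    header <- c(header, paste0("# fitness: ", format(model$fitness, digits = 15)))
  }
  if (!is.null(seed)) header <- c(header, paste0("# seed: ", as.integer(seed)))
  writeLines(c(header, model_equations_text(model)), path)
  invisible(path)
}

#' Read a Boolean model from equation text (.bnm)
#'
#' Exact inverse of [write_model()]: round-trips link operators and
#' regulator order.
#'
#' @param path file in the equation dialect.
#' @return a `boolean_model` (with `fitness` restored from the header when
#'   present).
#' @export
read_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fitness <- NA_real_
  hdr <- grep("^# fitness:", lines)
  if (length(hdr) > 0) fitness <- as.numeric(sub("^# fitness:", "", lines[hdr[1]]))
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) stop("no equations in model file: ", path)

  parse_group <- function(txt, lineno) {
    txt <- trimws(txt)
    if (!startsWith(txt, "(") || !endsWith(txt, ")")) {
      stop("model line ", lineno, ": malformed regulator group '", txt, "'")
    }
    inner <- substr(txt, 2, nchar(txt) - 1)
    parts <- trimws(strsplit(inner, " or ", fixed = TRUE)[[1]])
    ok <- grepl("^\\([^()]+\\)$", parts)
    if (length(parts) == 0 || !all(ok)) {
      stop("model line ", lineno, ": malformed regulator group '", txt, "'")
    }
    substr(parts, 2, nchar(parts) - 1)
  }

  eqs <- lapply(seq_along(keep), function(i) {
    line <- lines[keep[i]]
    halves <- strsplit(line, " *= ", fixed = TRUE)[[1]]
    if (length(halves) != 2 || !nzchar(trimws(halves[1]))) {
      stop("model line ", keep[i], ": expected 'TARGET *= <equation>'")
    }
    target <- trimws(halves[1])
    rhs <- trimws(halves[2])
    if (grepl(") and not (", rhs, fixed = TRUE)) {
      gg <- strsplit(rhs, ") and not (", fixed = TRUE)[[1]]
      if (length(gg) != 2) stop("model line ", keep[i], ": malformed equation")
      list(target = target,
           act = parse_group(paste0(gg[1], ")"), keep[i]),
           inh = parse_group(paste0("(", gg[2]), keep[i]), op = .OP_AND_NOT)
    } else if (grepl(") or not (", rhs, fixed = TRUE)) {
      gg <- strsplit(rhs, ") or not (", fixed = TRUE)[[1]]
      if (length(gg) != 2) stop("model line ", keep[i], ": malformed equation")
      list(target = target,
           act = parse_group(paste0(gg[1], ")"), keep[i]),
           inh = parse_group(paste0("(", gg[2]), keep[i]), op = .OP_OR_NOT)
    } else if (startsWith(rhs, "not ")) {
      list(target = target, act = character(),
           inh = parse_group(substr(rhs, 5, nchar(rhs)), keep[i]), op = .OP_NONE)
    } else {
      list(target = target, act = parse_group(rhs, keep[i]),
           inh = character(), op = .OP_NONE)
    }
  })
  nodes <- vapply(eqs, `[[`, character(1), "target")
  if (anyDuplicated(nodes)) {
    stop("duplicate equation for node: ", nodes[duplicated(nodes)][1])
  }
  regs <- unique(unlist(lapply(eqs, function(e) c(e$act, e$inh))))
  unknown <- setdiff(regs, nodes)
  if (length(unknown) > 0) {
    stop("model references regulator(s) without an equation: ",
         paste(unknown, collapse = ", "))
  }
  act <- lapply(eqs, function(e) match(e$act, nodes))
  inh <- lapply(eqs, function(e) match(e$inh, nodes))
  .new_boolean_model(nodes, act, inh, vapply(eqs, `[[`, integer(1), "op"),
                     fitness = fitness,
                     provenance = list(origin = path))
}

#' Write an ensemble of models to a directory
#' @param ensemble an [evolve()] result (or plain list of models).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  models <- if (inherits(ensemble, "model_ensemble")) ensemble$models else ensemble
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(models)) {
    write_model(models[[i]], file.path(dir, sprintf("model_%04d.bnm", i)))
  }
  if (inherits(ensemble, "model_ensemble") && !is.null(ensemble$log)) {
    utils::write.table(ensemble$log, file.path(dir, "training_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read an ensemble of models from a directory of .bnm files
#' @param dir directory containing `*.bnm` files.
#' @return list of `boolean_model` objects, in file order.
#' @export
read_ensemble <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.bnm$", full.names = TRUE))
  if (length(files) == 0) stop("no .bnm model files in ", dir)
  lapply(files, read_model)
}
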