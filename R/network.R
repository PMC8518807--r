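#' Mass-action reaction networks
#'
#' A `reaction_network` holds an ordered species table, an ordered list of
#' *unidirectional* mass-action reactions (reversible steps are stored as a
#' forward/reverse pair sharing a `pair_id`, in the spirit of stoichiometric
#' network analysis where the two directions are distinct reactions), the
#' temperature, and an ideal-CSTR exchange configuration: one dilution rate
#' `flow_rate` applied to every `exchanged` species, each with its own inflow
#' concentration.  Species may instead be `clamped` (held at a fixed
#' concentration); thermodynamic reports on clamped networks carry a caveat
#' because the entropy carried by the implicit chemostats is not modeled.
#'
#' Networks are normally built by [parse_network()] / [read_network()] or by
#' the preset constructors ([make_ab()], [make_competitive()],
#' [make_schlogl()], [make_frank()], [random_network()]).
#'
#' @section Fields:
#' \describe{
#'   \item{species}{data.frame with columns `name`, `init` (mol/L),
#'     `exchanged`, `inflow` (mol/L), `clamped`.}
#'   \item{reactions}{list of unidirectional reactions; each has `name`,
#'     `reactants` and `products` (named non-negative integer vectors),
#'     `k` (mass-action constant), `pair_id` (`NA` for a strictly
#'     irreversible step) and `direction`.}
#'   \item{temperature}{K.}
#'   \item{flow_rate}{CSTR dilution rate, 1/s (0 for a closed system).}
#' }
#' Compiled alongside: reactant/product stoichiometry matrices `Mr`, `Mp`
#' (species x reactions), the net stoichiometric matrix `N = Mp - Mr`, the
#' rate-constant vector `k`, and a `pairs` table mapping each `pair_id` to
#' its forward and reverse column indices.
#'
#' @name reaction_network
NULL

new_species <- function(name, init = 0, exchanged = FALSE, inflow = 0,
                        clamped = FALSE) {
  data.frame(name = name, init = init, exchanged = exchanged,
             inflow = inflow, clamped = clamped, stringsAsFactors = FALSE)
}

## Internal constructor: validates and compiles.
new_reaction_network <- function(species, reactions, temperature = 300,
                                 flow_rate = 0) {
  net <- structure(list(species = species, reactions = reactions,
                        temperature = temperature, flow_rate = flow_rate),
                   class = "reaction_network")
  validate_network(net)
  compile_network(net)
}

validate_network <- function(net) {
  sp <- net$species
  if (anyDuplicated(sp$name))
    stop("duplicate species name: ", sp$name[duplicated(sp$name)][1])
  if (any(sp$init < 0)) stop("negative initial concentration")
  if (any(sp$inflow < 0)) stop("negative inflow concentration")
  if (any(sp$exchanged & sp$clamped))
    stop("species cannot be both clamped and exchanged: ",
         sp$name[sp$exchanged & sp$clamped][1])
  if (!is.finite(net$temperature) || net$temperature <= 0)
    stop("temperature must be positive")
  if (net$flow_rate < 0) stop("flow_rate must be >= 0")
  if (net$flow_rate > 0 && !any(sp$exchanged))
    stop("flow_rate > 0 requires at least one exchanged species")
  seen_pairs <- list()
  for (r in net$reactions) {
    for (side in list(r$reactants, r$products)) {
      if (length(side)) {
        if (any(!names(side) %in% sp$name))
          stop("unknown species in reaction ", r$name, ": ",
               setdiff(names(side), sp$name)[1])
        if (any(side != round(side)) || any(side < 0))
          stop("stoichiometric coefficients must be non-negative integers (",
               r$name, ")")
        if (any(side > 4))
          stop("stoichiometric coefficient > 4 in reaction ", r$name)
      }
    }
    if (length(r$reactants) == 0 && length(r$products) == 0)
      stop("reaction ", r$name, " has neither reactants nor products")
    if (!is.finite(r$k) || r$k <= 0)
      stop("non-positive rate constant in reaction ", r$name)
  }
  ## pairing: both directions present and mirrored
  pids <- vapply(net$reactions, function(r) r$pair_id %||% NA_character_,
                 character(1))
  for (pid in unique(pids[!is.na(pids)])) {
    idx <- which(pids == pid)
    if (length(idx) != 2)
      stop("pair '", pid, "' must have exactly a forward and a reverse step")
    dirs <- vapply(net$reactions[idx], `[[`, character(1), "direction")
    if (!setequal(dirs, c("forward", "reverse")))
      stop("pair '", pid, "' needs one forward and one reverse step")
    f <- net$reactions[[idx[dirs == "forward"]]]
    b <- net$reactions[[idx[dirs == "reverse"]]]
    if (!same_side(f$reactants, b$products) ||
        !same_side(f$products, b$reactants))
      stop("pair '", pid, "' reverse step does not mirror the forward step")
  }
  invisible(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

same_side <- function(x, y) {
  x <- x[x != 0]; y <- y[y != 0]
  length(x) == length(y) && setequal(names(x), names(y)) &&
    all(x[names(y)] == y)
}

compile_network <- function(net) {
  spn <- net$species$name
  n_sp <- length(spn)
  n_rx <- length(net$reactions)
  Mr <- matrix(0, n_sp, n_rx, dimnames = list(spn, NULL))
  Mp <- matrix(0, n_sp, n_rx, dimnames = list(spn, NULL))
  k <- numeric(n_rx)
  rxn_names <- character(n_rx)
  for (j in seq_len(n_rx)) {
    r <- net$reactions[[j]]
    if (length(r$reactants)) Mr[names(r$reactants), j] <- r$reactants
    if (length(r$products))  Mp[names(r$products), j] <- r$products
    k[j] <- r$k
    rxn_names[j] <- r$name
  }
  colnames(Mr) <- colnames(Mp) <- rxn_names
  pids <- vapply(net$reactions, function(r) r$pair_id %||% NA_character_,
                 character(1))
  dirs <- vapply(net$reactions, `[[`, character(1), "direction")
  upids <- unique(pids[!is.na(pids)])
  pairs <- data.frame(id = upids,
                      fwd = vapply(upids, function(p)
                        which(pids == p & dirs == "forward"), integer(1)),
                      rev = vapply(upids, function(p)
                        which(pids == p & dirs == "reverse"), integer(1)),
                      stringsAsFactors = FALSE)
  net$Mr <- Mr
  net$Mp <- Mp
  net$N <- Mp - Mr
  net$k <- k
  net$pairs <- pairs
  ## reactions not belonging to any pair: dynamics-only, no affinity defined
  net$unpaired <- which(is.na(pids))
  net
}

n_species <- function(net) nrow(net$species)
n_reactions <- function(net) length(net$reactions)

#' Is every reaction part of a reversible pair?
#'
#' Thermodynamic operations (affinities, entropy production, GEC) require a
#' reverse partner for every step: the affinity `RT*log(vf/vr)` is undefined
#' when a direction is missing.  Networks with strictly irreversible steps
#' are accepted for dynamics only.
#'
#' @param net a `reaction_network`.
#' @return logical scalar.
#' @export
is_thermo_complete <- function(net) length(net$unpaired) == 0

stop_if_thermo_incomplete <- function(net) {
  if (!is_thermo_complete(net))
    stop("network is thermodynamically incomplete: reaction(s) ",
         paste(vapply(net$reactions[net$unpaired], `[[`, character(1), "name"),
               collapse = ", "),
         " have no reverse partner, so affinities are undefined")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:", n_species(x), "species,",
      nrow(x$pairs), "reversible pair(s)",
      if (length(x$unpaired)) paste0("+ ", length(x$unpaired),
                                     " irreversible step(s)") else "",
      "\n")
  cat("  T =", x$temperature, "K;",
      if (x$flow_rate > 0) paste0("open CSTR, flow = ", x$flow_rate, " /s")
      else "closed system", "\n")
  sp <- x$species
  tag <- ifelse(sp$clamped, " [clamped]",
                ifelse(sp$exchanged, paste0(" [exchanged, inflow=",
                                            sp$inflow, "]"), ""))
  cat(paste0("  ", sp$name, " init=", sp$init, tag), sep = "\n")
  for (r in x$reactions) {
    cat("  ", r$name, ": ", side_string(r$reactants), " -> ",
        side_string(r$products), "  k=", r$k, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.reaction_network <- function(object, ...) {
  cl <- conservation_laws(object)
  cat("reaction_network with", n_species(object), "species and",
      n_reactions(object), "unidirectional reactions\n")
  cat("thermodynamically complete:", is_thermo_complete(object), "\n")
  cat("conserved moieties:", ncol(cl), "\n")
  if (any(object$species$clamped))
    cat("NOTE: clamped species present; thermodynamic balances are reported",
        "under the clamped-scenario caveat\n")
  invisible(object)
}

side_string <- function(side) {
  side <- side[side != 0]
  if (!length(side)) return("0")
  paste(ifelse(side == 1, names(side), paste(side, names(side))),
        collapse = " + ")
}

## ---------------------------------------------------------------------------
## Text format
##
##   # comment
##   species A init=1.0 exchanged inflow=1.0
##   species B init=0.0 clamped
##   reaction R1: A <-> B ; kf=2.0, kr=1.0
##   reaction R2: A + L -> 2 L ; kf=0.5
##   system T=300 flow=0.5
## ---------------------------------------------------------------------------

#' Parse a plain-text network description
#'
#' Line-oriented format with three statement types: `species`, `reaction`,
#' and `system` (see the package vignette).  Reversible arrows `<->` expand
#' into two unidirectional reactions sharing the statement label as their
#' `pair_id`; `->` declares a strictly irreversible step, accepted for
#' dynamics but rejected by thermodynamic operations.
#'
#' @param text character vector of lines, or one string with embedded
#'   newlines.
#' @return a validated [reaction_network].
#' @seealso [read_network()], [write_network()], [format_network()]
#' @export
#' @examples
#' net <- parse_network(c("species A init=1", "species B init=0",
#'                        "reaction R1: A <-> B ; kf=2, kr=1",
#'                        "system T=300 flow=0"))
#' net
parse_network <- function(text) {
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  species <- new_species(character(0), numeric(0), logical(0), numeric(0),
                         logical(0))
  reactions <- list()
  temperature <- 300
  flow <- 0
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[i])
    line <- trimws(line)
    if (line == "") next
    perr <- function(msg) stop("line ", i, ": ", msg, call. = FALSE)
    if (grepl("^species\\b", line)) {
      species <- rbind(species, parse_species_line(line, perr))
    } else if (grepl("^reaction\\b", line)) {
      reactions <- c(reactions, parse_reaction_line(line, perr))
    } else if (grepl("^system\\b", line)) {
      kv <- parse_kv(sub("^system\\s*", "", line), perr)
      if (!is.na(kv["T"])) temperature <- kv[["T"]]
      if (!is.na(kv["flow"])) flow <- kv[["flow"]]
    } else perr(paste0("unrecognized statement: '", line, "'"))
  }
  ids <- vapply(reactions, function(r) r$pair_id %||% NA_character_,
                character(1))
  ids <- ids[!is.na(ids)]
  if (anyDuplicated(ids[!duplicated(ids)])) stop("duplicate pair id")
  new_reaction_network(species, reactions, temperature, flow)
}

parse_species_line <- function(line, perr) {
  toks <- strsplit(trimws(sub("^species\\s+", "", line)), "\\s+")[[1]]
  if (!length(toks)) perr("species statement needs a name")
  name <- toks[1]
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    perr(paste0("invalid species name '", name, "'"))
  init <- 0; exchanged <- FALSE; inflow <- 0; clamped <- FALSE
  for (t in toks[-1]) {
    if (t == "exchanged") exchanged <- TRUE
    else if (t == "clamped") clamped <- TRUE
    else if (grepl("^init=", t)) init <- parse_number(sub("^init=", "", t), perr)
    else if (grepl("^inflow=", t)) inflow <- parse_number(sub("^inflow=", "", t), perr)
    else perr(paste0("unknown species attribute '", t, "'"))
  }
  new_species(name, init, exchanged, inflow, clamped)
}

parse_reaction_line <- function(line, perr) {
  m <- regmatches(line, regexec(
    "^reaction\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s*:\\s*(.*?)\\s*;\\s*(.*)$", line))[[1]]
  if (length(m) != 4) perr("malformed reaction statement")
  label <- m[2]; eqn <- m[3]; consts <- parse_kv(m[4], perr)
  reversible <- grepl("<->", eqn, fixed = TRUE)
  sides <- strsplit(eqn, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) perr("reaction needs exactly one arrow")
  lhs <- parse_side(sides[1], perr)
  rhs <- parse_side(sides[2], perr)
  if (is.na(consts["kf"])) perr("missing kf")
  kf <- consts[["kf"]]
  if (reversible) {
    if (is.na(consts["kr"])) perr("reversible reaction missing kr")
    list(list(name = paste0(label, ".f"), reactants = lhs, products = rhs,
              k = kf, pair_id = label, direction = "forward"),
         list(name = paste0(label, ".r"), reactants = rhs, products = lhs,
              k = consts[["kr"]], pair_id = label, direction = "reverse"))
  } else {
    if (!is.na(consts["kr"])) perr("irreversible reaction must not carry kr")
    list(list(name = label, reactants = lhs, products = rhs,
              k = kf, pair_id = NULL, direction = "forward"))
  }
}

parse_side <- function(s, perr) {
  s <- trimws(s)
  if (s == "" || s == "0") return(stats::setNames(integer(0), character(0)))
  out <- integer(0)
  for (term in strsplit(s, "+", fixed = TRUE)[[1]]) {
    m <- regmatches(term, regexec(
      "^\\s*([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*$", term))[[1]]
    if (length(m) != 3) perr(paste0("cannot parse term '", trimws(term), "'"))
    coef <- if (m[2] == "") 1L else as.integer(m[2])
    sp <- m[3]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + coef
  }
  out
}

parse_kv <- function(s, perr) {
  out <- c()
  s <- trimws(s)
  if (s == "") return(out)
  for (t in strsplit(s, "[,[:space:]]+")[[1]]) {
    if (t == "") next
    kv <- strsplit(t, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) perr(paste0("expected key=value, got '", t, "'"))
    out[kv[1]] <- parse_number(kv[2], perr)
  }
  out
}

parse_number <- function(s, perr) {
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x)) perr(paste0("invalid number '", s, "'"))
  x
}

#' Serialize a network to its text format
#'
#' The serializer emits the canonical dialect (species then reactions then
#' the system line, 17 significant digits) so that parse -> serialize ->
#' parse is the identity and equal networks serialize bit-identically.
#'
#' @param net a [reaction_network].
#' @return character vector of lines.
#' @export
format_network <- function(net) {
  sp <- net$species
  out <- character(0)
  for (i in seq_len(nrow(sp))) {
    l <- paste0("species ", sp$name[i], " init=", fmt_num(sp$init[i]))
    if (sp$exchanged[i])
      l <- paste0(l, " exchanged inflow=", fmt_num(sp$inflow[i]))
    if (sp$clamped[i]) l <- paste0(l, " clamped")
    out <- c(out, l)
  }
  done <- logical(n_reactions(net))
  for (j in seq_len(n_reactions(net))) {
    if (done[j]) next
    r <- net$reactions[[j]]
    if (!is.null(r$pair_id)) {
      prow <- net$pairs[net$pairs$id == r$pair_id, ]
      f <- net$reactions[[prow$fwd]]; b <- net$reactions[[prow$rev]]
      out <- c(out, paste0("reaction ", r$pair_id, ": ",
                           side_string(f$reactants), " <-> ",
                           side_string(f$products),
                           " ; kf=", fmt_num(f$k), ", kr=", fmt_num(b$k)))
      done[c(prow$fwd, prow$rev)] <- TRUE
    } else {
      out <- c(out, paste0("reaction ", r$name, ": ",
                           side_string(r$reactants), " -> ",
                           side_string(r$products), " ; kf=", fmt_num(r$k)))
      done[j] <- TRUE
    }
  }
  c(out, paste0("system T=", fmt_num(net$temperature),
                " flow=", fmt_num(net$flow_rate)))
}

#' @rdname parse_network
#' @param path file path.
#' @export
read_network <- function(path) parse_network(readLines(path))

#' @rdname format_network
#' @param path file path to write to.
#' @export
write_network <- function(net, path) {
  writeLines(format_network(net), path)
  invisible(path)
}

#' Initial concentration vector of a network
#' @param net a [reaction_network].
#' @return named numeric vector (mol/L) in species order.
#' @export
initial_state <- function(net) {
  stats::setNames(net$species$init, net$species$name)
}

## Resolve a parameter path used by scan_branch / the CLI:
##   "flow", "kf:R1", "kr:R1", "k:R2" (unidirectional), "inflow:A",
##   "clamp:A", "init:A"
set_parameter <- function(net, name, value) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  key <- parts[1]
  if (key == "flow") {
    net$flow_rate <- value
  } else if (key %in% c("kf", "kr", "k")) {
    lbl <- parts[2]
    hit <- FALSE
    for (j in seq_along(net$reactions)) {
      r <- net$reactions[[j]]
      if (key == "k" && r$name == lbl) { net$reactions[[j]]$k <- value; hit <- TRUE }
      if (key == "kf" && identical(r$pair_id, lbl) && r$direction == "forward") {
        net$reactions[[j]]$k <- value; hit <- TRUE }
      if (key == "kr" && identical(r$pair_id, lbl) && r$direction == "reverse") {
        net$reactions[[j]]$k <- value; hit <- TRUE }
    }
    if (!hit) stop("no reaction matches parameter '", name, "'")
  } else if (key %in% c("inflow", "clamp", "init")) {
    i <- match(parts[2], net$species$name)
    if (is.na(i)) stop("unknown species in parameter '", name, "'")
    if (key == "inflow") net$species$inflow[i] <- value
    else net$species$init[i] <- value  # clamp level and init share storage
  } else stop("unknown parameter '", name, "'")
  validate_network(net)
  compile_network(net)
}
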