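# Extended-Newick (rich Newick) parsing and writing.
#
# Dialect: reticulation nodes are written twice with a shared "#H<k>" tag;
# per-edge fields are ":length:support:gamma" where the third field is the
# inheritance probability of that edge and the support field is ignored.
# Missing branch lengths default to 1 coalescent unit; missing inheritance
# probabilities default to an even 0.5/0.5 split.

parse_enewick_nw <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("empty extended-Newick string")
  if (!grepl(";$", s)) stop("extended Newick must end with ';'")
  s <- sub(";$", "", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[pos] else ""
  advance <- function() pos <<- pos + 1L
  expect <- function(ch) {
    if (peek() != ch)
      stop(sprintf("parse error at position %d: expected '%s', found '%s'",
                   pos, ch, peek()))
    advance()
  }
  read_token <- function() {
    stopchars <- c(":", ",", "(", ")", ";")
    out <- character(0)
    while (pos <= n && !(chars[pos] %in% stopchars)) {
      out <- c(out, chars[pos]); advance()
    }
    paste(out, collapse = "")
  }
  read_field <- function() {
    tok <- read_token()
    if (!nzchar(tok)) return(NA_real_)
    val <- suppressWarnings(as.numeric(tok))
    if (is.na(val))
      stop(sprintf("parse error: '%s' is not a number", tok))
    val
  }

  nextid <- 0L
  labels <- character(0)      # by node id; NA for internal nodes
  new_node <- function() {
    nextid <<- nextid + 1L
    labels[nextid] <<- NA_character_
    nextid
  }
  et <- integer(0); eh <- integer(0); el <- numeric(0); eg <- numeric(0)
  hmap <- new.env(parent = emptyenv())   # "#H1" -> node id
  hseen <- new.env(parent = emptyenv())  # "#H1" -> occurrence count
  hkids <- new.env(parent = emptyenv())  # "#H1" -> TRUE once children attached

  parse_node <- function() {
    kids <- list()
    if (peek() == "(") {
      advance()
      repeat {
        kids[[length(kids) + 1L]] <- parse_node()
        if (peek() == ",") advance() else break
      }
      expect(")")
    }
    label <- read_token()
    len <- NA_real_; gam <- NA_real_
    if (peek() == ":") {
      advance(); len <- read_field()
      if (peek() == ":") {
        advance(); read_field()               # support, ignored
        if (peek() == ":") { advance(); gam <- read_field() }
      }
    }
    if (grepl("#", label, fixed = TRUE)) {
      htag <- sub("^[^#]*", "", label)
      if (!grepl("^#[A-Za-z]*[0-9]+$", htag))
        stop(sprintf("malformed reticulation tag '%s'", htag))
      if (exists(htag, envir = hmap)) {
        id <- get(htag, envir = hmap)
        assign(htag, get(htag, envir = hseen) + 1L, envir = hseen)
      } else {
        id <- new_node()
        assign(htag, id, envir = hmap)
        assign(htag, 1L, envir = hseen)
      }
      if (length(kids)) {
        if (exists(htag, envir = hkids))
          stop(sprintf("reticulation tag '%s' carries children at both occurrences",
                       htag))
        assign(htag, TRUE, envir = hkids)
      }
    } else {
      id <- new_node()
      if (!length(kids)) {
        if (!nzchar(label)) stop("unlabeled leaf in extended Newick")
        labels[id] <<- label
      }
    }
    for (k in kids) {
      et <<- c(et, id); eh <<- c(eh, k$id)
      el <<- c(el, k$len); eg <<- c(eg, k$gam)
    }
    list(id = id, len = len, gam = gam)
  }

  root <- parse_node()$id
  if (pos <= n)
    stop(sprintf("parse error: trailing text starting at '%s'", peek()))
  for (htag in ls(hmap)) {
    cnt <- get(htag, envir = hseen)
    if (cnt != 2L)
      stop(sprintf("reticulation tag '%s' appears %d time(s), expected 2", htag, cnt))
    if (!exists(htag, envir = hkids))
      stop(sprintf("reticulation tag '%s' has no child subtree", htag))
  }

  el[is.na(el)] <- 1.0
  leaf <- which(!is.na(labels))
  if (anyDuplicated(labels[leaf]))
    stop(sprintf("duplicate leaf label '%s'", labels[leaf][duplicated(labels[leaf])][1]))
  lab <- labels[leaf]
  names(lab) <- as.character(leaf)

  nw <- new_nw(cbind(et, eh), el, rep(NA_real_, length(et)), lab, root)

  # resolve inheritance probabilities on reticulation in-edges
  for (v in nw_retic_nodes(nw)) {
    ein <- which(nw$edge[, 2] == v)
    g <- eg[ein]
    if (all(is.na(g))) g <- c(0.5, 0.5)
    else if (is.na(g[1])) g[1] <- 1 - g[2]
    else if (is.na(g[2])) g[2] <- 1 - g[1]
    else if (abs(sum(g) - 1) > 1e-6)
      stop(sprintf("inheritance probabilities at a reticulation sum to %g, expected 1",
                   sum(g)))
    nw$gamma[ein] <- g / sum(g)
  }
  viol <- nw_validate(nw)
  if (nrow(viol))
    stop(sprintf("parsed graph is not a valid phylogenetic network: %s",
                 paste(sprintf("[%s] %s", viol$kind, viol$detail), collapse = "; ")))
  nw
}

fmt_num <- function(x) sprintf("%.12g", x)

write_enewick_nw <- function(nw, lengths = TRUE, gammas = TRUE) {
  # canonical child ordering by the sorted leaf-label cluster under each node
  ids <- nw_ids(nw)
  cluster <- new.env(parent = emptyenv())
  clus <- function(v) {
    key <- as.character(v)
    if (!is.null(cluster[[key]])) return(cluster[[key]])
    ch <- nw_children(nw, v)
    val <- if (!length(ch)) nw$label[[as.character(v)]]
           else paste(sort(unique(unlist(lapply(ch, clus)))), collapse = "\r")
    cluster[[key]] <- val
    val
  }
  for (v in ids) clus(v)

  hnum <- new.env(parent = emptyenv())
  hcount <- 0L
  retics <- nw_retic_nodes(nw)

  edge_fields <- function(i) {
    out <- ""
    if (lengths) out <- paste0(":", fmt_num(nw$len[i]))
    if (gammas && !is.na(nw$gamma[i])) {
      if (!lengths) out <- ":"
      out <- paste0(out, "::", fmt_num(nw$gamma[i]))
    }
    out
  }

  visit <- function(v, inrow) {
    fields <- if (length(inrow)) edge_fields(inrow) else ""
    if (v %in% retics) {
      key <- as.character(v)
      if (!is.null(hnum[[key]]))
        return(paste0("#H", hnum[[key]], fields))
      hcount <<- hcount + 1L
      myn <- hcount
      hnum[[key]] <- myn
      ch <- nw_children(nw, v)
      sub <- visit(ch[1], edge_row(nw, v, ch[1]))
      return(paste0("(", sub, ")#H", myn, fields))
    }
    ch <- nw_children(nw, v)
    if (!length(ch))
      return(paste0(nw$label[[as.character(v)]], fields))
    ord <- order(vapply(ch, clus, ""))
    parts <- vapply(ch[ord], function(c2) visit(c2, edge_row(nw, v, c2)), "")
    paste0("(", paste(parts, collapse = ","), ")", fields)
  }
  paste0(visit(nw$root, integer(0)), ";")
}
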