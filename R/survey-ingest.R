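#' Read sociometric survey tables
#'
#' The roster CSV has columns `id`, `surname_paternal`,
#' `surname_maternal`, `classroom`, `grade`; the nominations CSV has
#' columns `subject`, `target`, `relation` with relation one of
#' `friend`, `enemy`, `sibling`, `cousin`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_roster <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "surname_paternal", "surname_maternal", "classroom",
            "grade")
  if (!all(need %in% names(r)))
    stop_bad_arg("roster must have columns: ", paste(need, collapse = ", "))
  validate_roster(r)
}

#' @rdname read_roster
#' @export
read_nominations <- function(path) {
  nm <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("subject", "target", "relation")
  if (!all(need %in% names(nm)))
    stop_bad_arg("nominations must have columns: ",
                 paste(need, collapse = ", "))
  validate_nominations(nm)
}

validate_roster <- function(roster) {
  if (anyDuplicated(roster$id))
    stop_bad_arg("duplicate student id in roster: ",
                 roster$id[duplicated(roster$id)][1])
  if (any(!nzchar(roster$classroom)))
    stop_bad_arg("empty classroom id in roster")
  roster
}

validate_nominations <- function(nominations, roster = NULL) {
  ok_rel <- c("friend", "enemy", "sibling", "cousin")
  bad <- which(!nominations$relation %in% ok_rel)
  if (length(bad))
    stop_bad_arg("unknown relation in nomination row ", bad[1], ": ",
                 nominations$relation[bad[1]])
  bad <- which(nominations$subject == nominations$target)
  if (length(bad))
    stop_bad_arg("self-nomination in row ", bad[1])
  if (!is.null(roster)) {
    bad <- which(!(nominations$subject %in% roster$id &
                   nominations$target %in% roster$id))
    if (length(bad))
      stop_bad_arg("nomination row ", bad[1],
                   " references an id missing from the roster (",
                   nominations$subject[bad[1]], " -> ",
                   nominations$target[bad[1]], ")")
  }
  nominations
}

norm_surname <- function(x) tolower(trimws(x))

#' Infer kinship from sibling/cousin nominations and surnames
#'
#' Applies the survey consistency rules: two students are siblings when
#' at least one nominates the other as a sibling *and* both surnames
#' (paternal and maternal) match; cousins when at least one nominates
#' the other as a cousin *and* they share at least one surname. The
#' relations are then closed to a fixpoint: siblingship is symmetric and
#' transitive, cousinship is symmetric, and a cousin of a sibling is a
#' cousin. Where both would hold, siblingship takes precedence.
#' Surname comparison is exact after case-folding and whitespace
#' trimming. Young children often omit kin ties, which is why one
#' nomination plus surname evidence suffices.
#'
#' @param roster Roster data frame (see [read_roster()]).
#' @param nominations Nominations data frame.
#' @return A list of symmetric 0/1 matrices `sibling`, `cousin` and
#'   `kinship` (their union), with student ids as dimnames.
#' @export
infer_kinship <- function(roster, nominations) {
  roster <- validate_roster(roster)
  nominations <- validate_nominations(nominations, roster)
  ids <- roster$id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  pat <- norm_surname(roster$surname_paternal)
  mat <- norm_surname(roster$surname_maternal)
  sib <- matrix(0L, n, n, dimnames = list(ids, ids))
  cou <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (r in which(nominations$relation %in% c("sibling", "cousin"))) {
    i <- idx[[nominations$subject[r]]]
    j <- idx[[nominations$target[r]]]
    both_match <- pat[i] == pat[j] && mat[i] == mat[j]
    any_match <- any(c(pat[i], mat[i]) %in% c(pat[j], mat[j]))
    if (nominations$relation[r] == "sibling" && both_match)
      sib[i, j] <- sib[j, i] <- 1L
    if (nominations$relation[r] == "cousin" && any_match)
      cou[i, j] <- cou[j, i] <- 1L
  }
  # closure to fixpoint: sibling transitivity, cousin-of-sibling
  for (iter in seq_len(n + 1L)) {
    sib2 <- sib | ((sib %*% sib) > 0)
    diag(sib2) <- FALSE
    cou2 <- cou | ((cou %*% sib2) > 0) | ((sib2 %*% cou) > 0)
    diag(cou2) <- FALSE
    sib2 <- sib2 * 1L; cou2 <- cou2 * 1L
    if (identical(sib2, sib) && identical(cou2, cou)) break
    sib <- sib2; cou <- cou2
  }
  cou[sib == 1L] <- 0L   # sibling precedence
  list(sibling = sib, cousin = cou,
       kinship = ((sib | cou) * 1L))
}

#' Build symmetric relationship matrices from survey nominations
#'
#' Friendship and enmity are bilateral: a tie requires both students to
#' nominate each other. Kinship ties (from [infer_kinship()]) are
#' included as friendships. The result is three symmetric 0/1 matrices
#' with zero diagonals; pairs that are simultaneously bilateral friends
#' and bilateral enemies are kept in both matrices and reported in
#' `conflicts`.
#'
#' @param roster Roster data frame.
#' @param nominations Nominations data frame.
#' @return An object of class `"relationship_matrices"`: a list with
#'   `friendship`, `enmity`, `kinship`, `sibling`, `cousin` matrices and
#'   a `conflicts` data frame.
#' @export
build_matrices <- function(roster, nominations) {
  roster <- validate_roster(roster)
  nominations <- validate_nominations(nominations, roster)
  kin <- infer_kinship(roster, nominations)
  ids <- roster$id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  nominated <- function(rel) {
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    rows <- which(nominations$relation == rel)
    m[cbind(idx[nominations$subject[rows]],
            idx[nominations$target[rows]])] <- 1L
    m
  }
  f1 <- nominated("friend")
  e1 <- nominated("enemy")
  friendship <- ((f1 & t(f1)) | kin$kinship) * 1L
  enmity <- (e1 & t(e1)) * 1L
  diag(friendship) <- 0L; diag(enmity) <- 0L
  both <- which(friendship == 1L & enmity == 1L, arr.ind = TRUE)
  both <- both[both[, 1] < both[, 2], , drop = FALSE]
  conflicts <- data.frame(id_a = ids[both[, 1]], id_b = ids[both[, 2]],
                          stringsAsFactors = FALSE)
  if (nrow(conflicts))
    warning(nrow(conflicts),
            " pair(s) are simultaneously bilateral friends and enemies")
  structure(list(friendship = friendship, enmity = enmity,
                 kinship = kin$kinship, sibling = kin$sibling,
                 cousin = kin$cousin, conflicts = conflicts),
            class = "relationship_matrices")
}

#' @export
print.relationship_matrices <- function(x, ...) {
  cnt <- function(m) sum(m) / 2
  cat(sprintf(
    "Relationship matrices over %d students: %d friendship, %d enmity, %d kinship pairs\n",
    nrow(x$friendship), cnt(x$friendship), cnt(x$enmity), cnt(x$kinship)))
  if (nrow(x$conflicts))
    cat("  ", nrow(x$conflicts), "friend/enemy conflict pair(s)\n")
  invisible(x)
}

#' Relationship matrix to graph
#'
#' @param x A `"relationship_matrices"` object.
#' @param relation Which matrix to convert.
#' @return A simple undirected igraph graph with student ids as names.
#' @export
relationship_graph <- function(x, relation = c("friendship", "enmity",
                                               "kinship")) {
  relation <- match.arg(relation)
  igraph::graph_from_adjacency_matrix(x[[relation]], mode = "undirected")
}

#' Generate a synthetic survey roster with nominations
#'
#' Emulates the structure of a sociometric school survey so the
#' matrix-building pipeline can be exercised without confidential data:
#' students carry paternal and maternal surnames drawn from a fixed
#' Spanish-surname pool, are assigned to balanced classrooms, and a
#' fraction of them belong to planted families — sibling pairs sharing
#' both surnames and cousin pairs sharing the paternal surname, each
#' pair emitting one kin nomination. Friend and enemy nominations are
#' drawn per student (Poisson counts), target classmates with
#' probability 0.9, and are reciprocated independently with probability
#' `reciprocity`.
#'
#' @param n_students Number of students.
#' @param n_classrooms Number of classrooms.
#' @param family_rate Fraction of students placed into a planted family
#'   pair.
#' @param friend_mean,enemy_mean Mean nominations emitted per student.
#' @param reciprocity Probability that a nomination is reciprocated.
#' @param seed Optional integer seed.
#' @return A list with data frames `roster` and `nominations`, plus
#'   `families` (the planted sibling/cousin pairs).
#' @examples
#' s <- synthetic_roster(60, 3, family_rate = 0.2, seed = 1)
#' head(s$nominations)
#' @export
synthetic_roster <- function(n_students, n_classrooms, family_rate = 0.1,
                             friend_mean = 6, enemy_mean = 1.2,
                             reciprocity = 0.7, seed = NULL) {
  n_students <- check_count(n_students, "n_students", min = 2L)
  n_classrooms <- check_count(n_classrooms, "n_classrooms", min = 1L)
  check_probability(reciprocity, "reciprocity")
  check_probability(family_rate, "family_rate")
  with_seed(seed, {
    pool <- c("Garcia", "Martinez", "Lopez", "Hernandez", "Gonzalez",
              "Perez", "Sanchez", "Ramirez", "Cruz", "Flores", "Gomez",
              "Diaz", "Reyes", "Torres", "Chan", "Pech", "Canul", "May",
              "Poot", "Uc", "Dzul", "Cauich", "Couoh", "Chi")
    ids <- sprintf("S%03d", seq_len(n_students))
    sizes <- classroom_sizes(n_students, n_classrooms)
    classroom <- rep(sprintf("C%02d", seq_len(n_classrooms)), sizes)
    grade <- rep(((seq_len(n_classrooms) - 1L) %% 6L) + 1L, sizes)
    pat <- sample(pool, n_students, replace = TRUE)
    mat <- sample(pool, n_students, replace = TRUE)
    # planted families: disjoint pairs, alternating sibling / cousin
    n_pairs <- floor(family_rate * n_students / 2)
    fam_members <- if (n_pairs > 0)
      sample.int(n_students, 2L * n_pairs) else integer(0)
    fam <- NULL
    noms <- list()
    for (f in seq_len(n_pairs)) {
      i <- fam_members[2L * f - 1L]; j <- fam_members[2L * f]
      type <- if (f %% 2L == 1L) "sibling" else "cousin"
      if (type == "sibling") {
        pat[j] <- pat[i]; mat[j] <- mat[i]
      } else {
        pat[j] <- pat[i]
        if (mat[j] == mat[i]) mat[j] <- pool[match(mat[i], pool) %% length(pool) + 1L]
      }
      noms[[length(noms) + 1L]] <-
        data.frame(subject = ids[i], target = ids[j], relation = type,
                   stringsAsFactors = FALSE)
      fam <- rbind(fam, data.frame(id_a = ids[i], id_b = ids[j],
                                   type = type, stringsAsFactors = FALSE))
    }
    # mutual nominations arise only through the reciprocation coin, so
    # `reciprocity` is exactly the bilateral-tie rate: a student never
    # spontaneously re-nominates someone already nominating them
    emit <- function(relation, mean_count) {
      seen <- new.env(hash = TRUE)
      key <- function(i, j) paste0(i, "|", j)
      for (i in seq_len(n_students)) {
        n_nom <- rpois(1L, mean_count)
        if (n_nom == 0L) next
        same <- setdiff(which(classroom == classroom[i]), i)
        other <- setdiff(seq_len(n_students), c(i, same))
        for (t in seq_len(n_nom)) {
          from_class <- length(same) > 0 &&
            (length(other) == 0 || runif(1) < 0.9)
          j <- if (from_class) sample(same, 1L)
               else if (length(other)) sample(other, 1L) else next
          if (exists(key(j, i), envir = seen, inherits = FALSE) ||
              exists(key(i, j), envir = seen, inherits = FALSE)) next
          assign(key(i, j), TRUE, envir = seen)
          noms[[length(noms) + 1L]] <<-
            data.frame(subject = ids[i], target = ids[j],
                       relation = relation, stringsAsFactors = FALSE)
          if (runif(1) < reciprocity) {
            assign(key(j, i), TRUE, envir = seen)
            noms[[length(noms) + 1L]] <<-
              data.frame(subject = ids[j], target = ids[i],
                         relation = relation, stringsAsFactors = FALSE)
          }
        }
      }
    }
    emit("friend", friend_mean)
    emit("enemy", enemy_mean)
    nominations <- unique(do.call(rbind, noms))
    rownames(nominations) <- NULL
    list(
      roster = data.frame(id = ids, surname_paternal = pat,
                          surname_maternal = mat, classroom = classroom,
                          grade = grade, stringsAsFactors = FALSE),
      nominations = nominations,
      families = fam
    )
  })
}
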