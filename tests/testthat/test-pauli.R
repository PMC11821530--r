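# Symplectic Pauli algebra against dense Kronecker-product oracles.

test_that("products carry exact phases on all 1- and 2-qubit pairs", {
  labs1 <- c("I", "X", "Y", "Z")
  for (a in labs1) for (b in labs1) {
    p <- pauliProduct(pauliTerm(a), pauliTerm(b))
    expect_lt(max(abs(kronPauliSum(p) - kronPauli(a) %*% kronPauli(b))),
              1e-12)
  }
  labs2 <- as.vector(outer(labs1, labs1, paste0))
  for (a in labs2) for (b in labs2) {
    p <- pauliProduct(pauliTerm(a), pauliTerm(b))
    expect_lt(max(abs(kronPauliSum(p) - kronPauli(a) %*% kronPauli(b))),
              1e-12)
  }
  # canonical singles
  expect_equal(pauliStrings(pauliProduct(pauliTerm("X"), pauliTerm("X"))),
               "I")
  zy <- pauliProduct(pauliTerm("Z"), pauliTerm("Y"))
  expect_equal(pauliStrings(zy), "X")
  expect_equal(coeffs(zy), as.complex(-1i))
})

test_that("string rendering puts qubit 0 leftmost", {
  p <- pauliTerm("XIZ")
  M <- kronPauli("XIZ")         # helper builds with qubit0 = lowest bit
  expect_lt(max(abs(pauliMatrix(p) - M)), 1e-12)
  expect_equal(pauliStrings(p), "XIZ")
})

test_that("commutation matches the dense commutator on random 3-qubit pairs",
{
  H1 <- randomPauliSum(3, 10, 11)
  H2 <- randomPauliSum(3, 10, 12)
  for (i in seq_len(nTerms(H1))) for (j in seq_len(nTerms(H2))) {
    A <- kronPauli(pauliStrings(H1)[i])
    B <- kronPauli(pauliStrings(H2)[j])
    dense <- max(abs(A %*% B - B %*% A)) < 1e-12
    expect_equal(unname(pauliCommutes(H1[i], H2[j])), dense)
  }
})

test_that("qubit-wise commutation implies commutation (exhaustive 2 qubits)",
{
  labs2 <- as.vector(outer(c("I", "X", "Y", "Z"), c("I", "X", "Y", "Z"),
                           paste0))
  for (a in labs2) for (b in labs2) {
    qw <- pauliQWCommutes(pauliTerm(a), pauliTerm(b))
    cm <- pauliCommutes(pauliTerm(a), pauliTerm(b))
    if (qw) expect_true(cm)
  }
  expect_true(pauliQWCommutes(pauliTerm("ZI"), pauliTerm("IZ")))
  expect_false(pauliQWCommutes(pauliTerm("XX"), pauliTerm("ZZ")))
  expect_true(pauliCommutes(pauliTerm("XX"), pauliTerm("ZZ")))
})

test_that("noncontextuality test handles the canonical sets", {
  expect_true(isNoncontextual(pauliSum(c("ZI", "IZ", "ZZ"), 1)))
  expect_true(isNoncontextual(pauliSum(c("X", "Y", "Z"), 1)))
  expect_false(isNoncontextual(pauliSum(c("XI", "ZI", "XX", "ZZ"), 1)))
})

test_that("noncontextuality is invariant under rescaling and reordering", {
  for (s in 1:5) {
    H <- randomPauliSum(4, 10, s)
    base <- isNoncontextual(H)
    resc <- newPauliSum(H@x, H@z, H@coeff * stats::runif(nTerms(H), 0.1, 5),
                        4L)
    expect_equal(isNoncontextual(resc), base)
    perm <- sample(nTerms(H))
    expect_equal(isNoncontextual(H[perm]), base)
  }
})

test_that("l1 norm is subadditive after canonicalization and sums moduli", {
  expect_equal(l1Norm(pauliSum(nQubits = 2L)), 0)
  expect_equal(l1Norm(pauliSum(c("X", "Z"), c(2, -3))), 5)
  for (s in 1:4) {
    H1 <- randomPauliSum(3, 8, s)
    H2 <- randomPauliSum(3, 8, s + 50)
    expect_lte(l1Norm(H1 + H2), l1Norm(H1) + l1Norm(H2) + 1e-12)
    expect_equal(l1Norm(H1), sum(Mod(coeffs(H1))))
  }
})

test_that("exact ground energies match small closed forms and dense oracles",
{
  expect_equal(groundEnergyExact(pauliSum("Z", 1)), -1)
  expect_equal(groundEnergyExact(pauliSum(c("X", "Z"), c(3, 4))), -5)
  H <- randomPauliSum(9, 40, 7)
  dense <- min(eigen(kronPauliSum(H), symmetric = TRUE)$values)
  expect_equal(groundEnergyExact(H), dense, tolerance = 1e-9)
})

test_that("random fixtures are reproducible and Hermitian", {
  A <- randomPauliSum(4, 12, 99)
  B <- randomPauliSum(4, 12, 99)
  expect_identical(pauliStrings(A), pauliStrings(B))
  expect_identical(coeffs(A), coeffs(B))
  expect_lte(nTerms(A), 12L)
  M <- kronPauliSum(A)
  expect_lt(max(abs(M - Conj(t(M)))), 1e-12)
})

test_that("text format round-trips bit-exactly on the string form", {
  H <- randomPauliSum(5, 15, 3)
  f <- withr::local_tempfile(fileext = ".txt")
  writePauliSum(H, f)
  H2 <- canonicalize(readPauliSum(f))
  expect_identical(pauliStrings(H2), pauliStrings(H))
  expect_equal(coeffs(H2), coeffs(H))
})

test_that("canonicalization merges duplicates and the matvec operator agrees
           with the dense matrix", {
  H <- pauliSum(c("XY", "XY", "ZI"), c(0.5, 0.25, -1))
  expect_equal(nTerms(H), 2L)
  Hr <- randomPauliSum(6, 25, 21)
  op <- pauliMatvecOperator(Hr)
  v <- complex(real = stats::rnorm(64), imaginary = stats::rnorm(64))
  expect_lt(max(Mod(op$matvec(v) - kronPauliSum(Hr) %*% v)), 1e-10)
})

test_that("dimension mismatches raise errors", {
  expect_error(pauliProduct(pauliTerm("X"), pauliTerm("XX")), "dimension")
  expect_error(pauliCommutes(pauliTerm("X"), pauliTerm("XX")), "dimension")
})
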