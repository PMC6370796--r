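#include <Rcpp.h>
using namespace Rcpp;

// Draw `size` individuals without replacement from categories whose current
// counts are `pool` (sequential conditional hypergeometric; exact
// multivariate hypergeometric overall). Writes the draw into `out`.
static void mvhyper_draw(const int *pool, int ncat, double total, int size,
                         int *out) {
    double rest = total;
    int k = size;
    for (int i = 0; i < ncat; ++i) {
        if (k <= 0) { out[i] = 0; continue; }
        rest -= pool[i];
        if (rest <= 0) { out[i] = k; k = 0; continue; }
        int x = (int) R::rhyper((double) pool[i], rest, (double) k);
        out[i] = x;
        k -= x;
    }
}

// [[Rcpp::export]]
IntegerMatrix C_rarefy(IntegerMatrix counts, int depth) {
    int nr = counts.nrow(), nc = counts.ncol();
    IntegerMatrix out(nr, nc);
    std::vector<int> col(nr), drawn(nr);
    for (int j = 0; j < nc; ++j) {
        double total = 0;
        for (int i = 0; i < nr; ++i) { col[i] = counts(i, j); total += col[i]; }
        mvhyper_draw(col.data(), nr, total, depth, drawn.data());
        for (int i = 0; i < nr; ++i) out(i, j) = drawn[i];
    }
    return out;
}

// One random table with the given margins, distributed as uniform
// permutation of individual labels (Fisher / multivariate hypergeometric);
// equivalent to Patefield-type fixed-margin sampling.
static void null_table(const std::vector<int> &rowT, const IntegerVector &colT,
                       std::vector<int> &rem, std::vector<int> &drawn,
                       int *tab /* nr x nc, column-major */) {
    int nr = (int) rowT.size(), nc = colT.size();
    double total = 0;
    for (int i = 0; i < nr; ++i) { rem[i] = rowT[i]; total += rowT[i]; }
    for (int j = 0; j < nc - 1; ++j) {
        mvhyper_draw(rem.data(), nr, total, colT[j], drawn.data());
        for (int i = 0; i < nr; ++i) {
            tab[j * nr + i] = drawn[i];
            rem[i] -= drawn[i];
        }
        total -= colT[j];
    }
    for (int i = 0; i < nr; ++i) tab[(nc - 1) * nr + i] = rem[i];
}

// [[Rcpp::export]]
IntegerMatrix C_null_table(IntegerVector rowTotals, IntegerVector colTotals) {
    int nr = rowTotals.size(), nc = colTotals.size();
    IntegerMatrix out(nr, nc);
    std::vector<int> rowT(rowTotals.begin(), rowTotals.end());
    std::vector<int> rem(nr), drawn(nr);
    null_table(rowT, colTotals, rem, drawn, INTEGER(out));
    return out;
}

static double hill_q(const int *x, int n, double total, int q) {
    if (q == 0) {
        int s = 0;
        for (int i = 0; i < n; ++i) if (x[i] > 0) ++s;
        return (double) s;
    }
    if (q == 1) {
        double h = 0;
        for (int i = 0; i < n; ++i)
            if (x[i] > 0) {
                double p = x[i] / total;
                h -= p * std::log(p);
            }
        return std::exp(h);
    }
    double s2 = 0;
    for (int i = 0; i < n; ++i) {
        double p = x[i] / total;
        s2 += p * p;
    }
    return 1.0 / s2;
}

// beta = 1 - mean(alpha)/gamma for `nIter` random fixed-margin tables of the
// observed block, for each order q; gamma is margin-determined, so constant.
// [[Rcpp::export]]
NumericMatrix C_null_beta(IntegerMatrix counts, IntegerVector qs, int nIter) {
    int nr = counts.nrow(), nc = counts.ncol(), nq = qs.size();
    std::vector<int> rowT(nr, 0);
    IntegerVector colT(nc);
    for (int j = 0; j < nc; ++j) {
        int cs = 0;
        for (int i = 0; i < nr; ++i) {
            rowT[i] += counts(i, j);
            cs += counts(i, j);
        }
        colT[j] = cs;
    }
    double grand = 0;
    for (int i = 0; i < nr; ++i) grand += rowT[i];
    std::vector<double> gamma(nq);
    for (int m = 0; m < nq; ++m)
        gamma[m] = hill_q(rowT.data(), nr, grand, qs[m]);

    NumericMatrix beta(nIter, nq);
    std::vector<int> tab(nr * nc), rem(nr), drawn(nr);
    for (int it = 0; it < nIter; ++it) {
        null_table(rowT, colT, rem, drawn, tab.data());
        for (int m = 0; m < nq; ++m) {
            double asum = 0;
            for (int j = 0; j < nc; ++j)
                asum += hill_q(tab.data() + j * nr, nr, (double) colT[j],
                               qs[m]);
            beta(it, m) = 1.0 - (asum / nc) / gamma[m];
        }
    }
    return beta;
}
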