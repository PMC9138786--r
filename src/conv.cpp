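#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Convolution + global-average-pooling reducer over the per-drug sequence
// matrices, in sparse patch layout: X stacks, drug by drug, the im2col rows
// of every patch position whose receptive field can be nonzero; positions
// whose field is entirely zero-padding contribute relu(bias) analytically
// (their count per drug is nzero). offsets are 0-based row offsets into X,
// length n+1. totalPos is the pooling denominator (lMax^2).
//
// The patch matrix is converted to single precision once and cached behind
// an external pointer: the conv GEMMs are memory-bandwidth-bound and fp32
// halves the traffic, while pooled sums and weight-gradient accumulation
// stay in double precision.

struct ConvCache {
    arma::fmat X;
    arma::ivec offsets;
    arma::ivec nzero;
};

// [[Rcpp::export(name = ".convCacheCreateCpp")]]
SEXP convCacheCreate(const arma::mat& X, const arma::ivec& offsets,
                     const arma::ivec& nzero) {
    ConvCache* c = new ConvCache;
    c->X = arma::conv_to<arma::fmat>::from(X);
    c->offsets = offsets;
    c->nzero = nzero;
    XPtr<ConvCache> p(c, true);
    return p;
}

// [[Rcpp::export(name = ".convCacheValidCpp")]]
bool convCacheValid(SEXP ptr) {
    XPtr<ConvCache> p(ptr);
    return p.get() != NULL;
}

// [[Rcpp::export(name = ".convGapForwardCpp")]]
arma::mat convGapForward(SEXP ptr, const arma::mat& W, const arma::vec& b,
                         const arma::uvec& idx, const int totalPos) {
    XPtr<ConvCache> c(ptr);
    const arma::uword m = idx.n_elem;
    const arma::uword K = W.n_cols;
    const arma::fmat fW = arma::conv_to<arma::fmat>::from(W);
    const arma::frowvec fb =
        arma::conv_to<arma::frowvec>::from(b.t());
    arma::vec reluB = arma::clamp(b, 0.0, arma::datum::inf);
    arma::mat out(m, K);
    arma::fmat A;
    for (arma::uword r = 0; r < m; ++r) {
        const arma::uword i = idx(r) - 1;  // 1-based from R
        const arma::uword lo = (arma::uword)c->offsets(i);
        const arma::uword hi = (arma::uword)c->offsets(i + 1);
        arma::rowvec pooled(K, arma::fill::zeros);
        if (hi > lo) {
            A = c->X.rows(lo, hi - 1) * fW;
            A.each_row() += fb;
            A.clamp(0.0f, arma::fdatum::inf);
            pooled = arma::conv_to<arma::rowvec>::from(arma::sum(A, 0));
        }
        out.row(r) = (pooled + (double)c->nzero(i) * reluB.t())
                     / (double)totalPos;
    }
    return out;
}

// Gradient w.r.t. W and b given upstream gradients G (m x K, rows aligned
// with idx). Activations are recomputed per drug in fp32; gradients are
// accumulated in double.

// [[Rcpp::export(name = ".convGapBackwardCpp")]]
List convGapBackward(SEXP ptr, const arma::mat& W, const arma::vec& b,
                     const arma::uvec& idx, const int totalPos,
                     const arma::mat& G) {
    XPtr<ConvCache> c(ptr);
    const arma::uword m = idx.n_elem;
    const arma::uword K = W.n_cols;
    const arma::fmat fW = arma::conv_to<arma::fmat>::from(W);
    const arma::frowvec fb = arma::conv_to<arma::frowvec>::from(b.t());
    arma::mat dW(W.n_rows, K, arma::fill::zeros);
    arma::vec db(K, arma::fill::zeros);
    arma::vec bPos = arma::conv_to<arma::vec>::from(b > 0);
    const double inv = 1.0 / (double)totalPos;
    arma::fmat A;
    for (arma::uword r = 0; r < m; ++r) {
        const arma::uword i = idx(r) - 1;
        const arma::uword lo = (arma::uword)c->offsets(i);
        const arma::uword hi = (arma::uword)c->offsets(i + 1);
        // zero-field positions: preactivation is exactly the bias
        db += (double)c->nzero(i) * inv * (bPos % G.row(r).t());
        if (hi == lo) continue;
        const arma::frowvec g =
            arma::conv_to<arma::frowvec>::from(inv * G.row(r));
        A = c->X.rows(lo, hi - 1) * fW;
        A.each_row() += fb;
        // dPre = 1[A > 0] * g, reusing A's storage
        A.transform([](float v) { return v > 0.0f ? 1.0f : 0.0f; });
        A.each_row() %= g;
        dW += arma::conv_to<arma::mat>::from(c->X.rows(lo, hi - 1).t() * A);
        db += arma::conv_to<arma::vec>::from(arma::sum(A, 0).t());
    }
    return List::create(Named("dW") = dW, Named("db") = db);
}

// Sequential edge-sampling SGD for the second-order LINE objective with
// negative sampling. Samples are pre-drawn (R's RNG, for reproducibility);
// updates are applied one sample at a time, each using the current
// parameter values, with the learning rate decaying linearly to 1e-4 of
// its initial value. src/dst/neg are 1-based; neg holds negK noise
// vertices per sample, sample-major.

// [[Rcpp::export(name = ".lineSgdCpp")]]
List lineSgd(arma::mat U, arma::mat Uc, const arma::uvec& src,
             const arma::uvec& dst, const arma::uvec& neg,
             const int negK, const double lr0) {
    const arma::uword T = src.n_elem;
    const arma::uword d = U.n_cols;
    arma::rowvec gi(d);
    for (arma::uword t = 0; t < T; ++t) {
        double lr = lr0 * (1.0 - (double)t / (double)T);
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        const arma::uword i = src(t) - 1;
        const arma::uword j = dst(t) - 1;
        gi.zeros();
        // positive context
        {
            double s = arma::dot(U.row(i), Uc.row(j));
            double g = 1.0 / (1.0 + std::exp(-s)) - 1.0;   // sigma(s) - 1
            gi -= g * Uc.row(j);
            Uc.row(j) -= lr * g * U.row(i);
        }
        // negative contexts
        for (int k = 0; k < negK; ++k) {
            const arma::uword m = neg(t * negK + k) - 1;
            double s = arma::dot(U.row(i), Uc.row(m));
            double g = 1.0 / (1.0 + std::exp(-s));          // sigma(s)
            gi -= g * Uc.row(m);
            Uc.row(m) -= lr * g * U.row(i);
        }
        U.row(i) += lr * gi;
    }
    return List::create(Named("U") = U, Named("Uc") = Uc);
}
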