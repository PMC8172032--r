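#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Best-matching unit per sample: squared-Euclidean nearest codebook column,
// ties broken by lowest neuron index. codebook and X are channels x units.
// [[Rcpp::export]]
IntegerVector cpp_find_bmu(NumericMatrix codebook, NumericMatrix X) {
    const int nch = codebook.nrow(), nneu = codebook.ncol(), ns = X.ncol();
    if (X.nrow() != nch) stop("channel dimension mismatch");
    IntegerVector out(ns);
    const double* W = &codebook(0, 0);
    for (int s = 0; s < ns; ++s) {
        const double* x = &X(0, s);
        double best = R_PosInf;
        int besti = 0;
        for (int j = 0; j < nneu; ++j) {
            const double* w = W + (size_t)j * nch;
            double d = 0.0;
            for (int c = 0; c < nch; ++c) {
                const double diff = x[c] - w[c];
                d += diff * diff;
            }
            if (d < best) { best = d; besti = j; }
        }
        out[s] = besti;  // 0-based; caller adjusts
    }
    return out;
}

// Online Kohonen training with class-augmented weight channels.
//  codebook: channels x neurons; classW: classes x neurons
//  X:        channels x samples; labels: 0-based class per sample
//  order:    samples x epochs matrix of 0-based presentation order
//  hexd2:    neurons x neurons squared hex-lattice distances
// Learning rate and radius decay exponentially over the full step count.
// Class channels are updated with the same neighbourhood factor scaled by
// classScale and never enter the BMU distance.  The hot loop runs in
// single precision (weight moves are O(1e-2) relative steps, far above
// float resolution); BMU search uses blocked partial-distance elimination
// and neighbourhood factors below 1e-4 are skipped.
// [[Rcpp::export]]
List cpp_train_som(NumericMatrix codebook, NumericMatrix classW,
                   NumericMatrix X, IntegerVector labels,
                   IntegerMatrix order, NumericMatrix hexd2,
                   double alpha0, double alphaF,
                   double sigma0, double sigmaF,
                   double classScale) {
    const int nch = codebook.nrow(), nneu = codebook.ncol();
    const int ncl = classW.nrow(), ns = X.ncol();
    const int nep = order.ncol();
    if (X.nrow() != nch) stop("channel dimension mismatch");
    if (order.nrow() != ns) stop("order/sample mismatch");
    std::vector<float> W(codebook.begin(), codebook.end());
    std::vector<float> C(classW.begin(), classW.end());
    std::vector<float> Xf(X.begin(), X.end());
    std::vector<float> hd2(hexd2.begin(), hexd2.end());
    NumericVector qe(nep);
    const double T = std::max(1.0, (double)nep * ns - 1.0);
    const double lr_ratio = std::log(alphaF / alpha0);
    const double sg_ratio = std::log(sigmaF / sigma0);
    double step = 0.0;
    for (int ep = 0; ep < nep; ++ep) {
        double qsum = 0.0;
        for (int t = 0; t < ns; ++t, step += 1.0) {
            const double frac = step / T;
            const float alpha = (float)(alpha0 * std::exp(lr_ratio * frac));
            const double sigma = sigma0 * std::exp(sg_ratio * frac);
            const float inv2s2 = (float)(1.0 / (2.0 * sigma * sigma));
            const int s = order(t, ep);
            const float* x = &Xf[(size_t)s * nch];
            const int lab = labels[s];
            // BMU on spectral channels, abandoning once past the best
            float best = 3.4e38f;
            int bmu = 0;
            for (int j = 0; j < nneu; ++j) {
                const float* w = &W[(size_t)j * nch];
                float d = 0.0f;
                int c = 0;
                bool alive = true;
                while (c < nch) {
                    const int stopc = std::min(c + 128, nch);
                    float acc = 0.0f;
                    for (; c < stopc; ++c) {
                        const float diff = x[c] - w[c];
                        acc += diff * diff;
                    }
                    d += acc;
                    if (d >= best) { alive = false; break; }
                }
                if (alive && d < best) { best = d; bmu = j; }
            }
            qsum += std::sqrt((double)best);
            const float* hd = &hd2[(size_t)bmu * nneu];
            for (int j = 0; j < nneu; ++j) {
                const float g = alpha * std::exp(-hd[j] * inv2s2);
                if (g < 1e-4f) continue;
                float* w = &W[(size_t)j * nch];
                for (int c = 0; c < nch; ++c) w[c] += g * (x[c] - w[c]);
                const float gc = (float)classScale * g;
                float* cw = &C[(size_t)j * ncl];
                for (int k = 0; k < ncl; ++k) {
                    const float target = (k == lab) ? 1.0f : 0.0f;
                    cw[k] += gc * (target - cw[k]);
                }
            }
        }
        qe[ep] = qsum / ns;
    }
    NumericMatrix Wout(nch, nneu), Cout(ncl, nneu);
    std::copy(W.begin(), W.end(), Wout.begin());
    std::copy(C.begin(), C.end(), Cout.begin());
    return List::create(_["codebook"] = Wout, _["classWeights"] = Cout,
                        _["qe"] = qe);
}
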