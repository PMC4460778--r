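"""Independent parametric empirical-Bayes ComBat oracle (no covariates).

Implements the published location/scale batch-adjustment model directly in
numpy, as a cross-language check of the R implementation.  Reads a TSV
(gene_id + sample columns; first half batch A, second half batch B as given
in the batches file) and writes the adjusted matrix.
"""
import sys
import numpy as np
import pandas as pd


def aprior(d):
    m, s2 = d.mean(), d.var(ddof=1)
    return (2 * s2 + m * m) / s2


def bprior(d):
    m, s2 = d.mean(), d.var(ddof=1)
    return (m * s2 + m ** 3) / s2


def combat(dat, batches, conv=1e-4):
    levels = sorted(set(batches), key=batches.index)
    n = dat.shape[1]
    nb = {b: sum(x == b for x in batches) for b in levels}
    idx = {b: [i for i, x in enumerate(batches) if x == b] for b in levels}

    batch_mean = np.column_stack([dat[:, idx[b]].mean(axis=1) for b in levels])
    w = np.array([nb[b] / n for b in levels])
    grand = batch_mean @ w
    fitted = np.column_stack([batch_mean[:, levels.index(b)] for b in batches])
    var_pooled = ((dat - fitted) ** 2).sum(axis=1) / n
    s = (dat - grand[:, None]) / np.sqrt(var_pooled)[:, None]

    adj = s.copy()
    for b in levels:
        sb = s[:, idx[b]]
        g_hat = sb.mean(axis=1)
        d_hat = sb.var(axis=1, ddof=1)
        g_bar, t2 = g_hat.mean(), g_hat.var(ddof=1)
        a, bp = aprior(d_hat), bprior(d_hat)
        g_new, d_new = g_hat.copy(), d_hat.copy()
        while True:
            g_old, d_old = g_new, d_new
            g_new = (t2 * nb[b] * g_hat + d_old * g_bar) / (t2 * nb[b] + d_old)
            sum2 = ((sb - g_new[:, None]) ** 2).sum(axis=1)
            d_new = (0.5 * sum2 + bp) / (nb[b] / 2 + a - 1)
            change = max(np.max(np.abs(g_new - g_old) / np.abs(g_old)),
                         np.max(np.abs(d_new - d_old) / np.abs(d_old)))
            if change < conv:
                break
        adj[:, idx[b]] = (sb - g_new[:, None]) / np.sqrt(d_new)[:, None]

    return adj * np.sqrt(var_pooled)[:, None] + grand[:, None]


def main(expr_path, meta_path, out_path):
    expr = pd.read_csv(expr_path, sep="\t", index_col=0)
    meta = pd.read_csv(meta_path, sep="\t")
    batches = [meta.set_index("sample_id").loc[s, "batch"]
               for s in expr.columns]
    adj = combat(expr.to_numpy(float), batches)
    out = pd.DataFrame(adj, index=expr.index, columns=expr.columns)
    out.to_csv(out_path, sep="\t", float_format="%.12g",
               index_label="gene_id")


if __name__ == "__main__":
    main(*sys.argv[1:4])
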