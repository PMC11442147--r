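"""Convert between AnnData h5ad files and the MTX triplet dialect.

Used by the R readers/writers so the package needs no R-side HDF5 stack.
Layout on the MTX side: matrix.mtx (genes x cells), features.tsv (id, symbol),
barcodes.tsv, cells.tsv (cell_id + obs columns).
"""
import sys
import os

import numpy as np
import pandas as pd
import scipy.io
import scipy.sparse as sp
import anndata as ad


def to_mtx(h5ad_path, outdir):
    adata = ad.read_h5ad(h5ad_path)
    os.makedirs(outdir, exist_ok=True)
    x = adata.X
    if not sp.issparse(x):
        x = sp.csr_matrix(np.asarray(x))
    # AnnData is cells x genes; MTX dialect stores genes x cells.
    scipy.io.mmwrite(os.path.join(outdir, "matrix.mtx"), x.T.tocoo())
    feats = pd.DataFrame({"id": adata.var_names, "symbol": adata.var_names})
    feats.to_csv(os.path.join(outdir, "features.tsv"), sep="\t",
                 header=False, index=False)
    pd.Series(adata.obs_names).to_csv(
        os.path.join(outdir, "barcodes.tsv"), sep="\t",
        header=False, index=False)
    cells = adata.obs.copy()
    cells.insert(0, "cell_id", adata.obs_names)
    cells.to_csv(os.path.join(outdir, "cells.tsv"), sep="\t", index=False)


def to_h5ad(mtxdir, h5ad_path):
    x = scipy.io.mmread(os.path.join(mtxdir, "matrix.mtx")).tocsr()
    feats = pd.read_csv(os.path.join(mtxdir, "features.tsv"), sep="\t",
                        header=None)
    bars = pd.read_csv(os.path.join(mtxdir, "barcodes.tsv"), sep="\t",
                       header=None)
    cells = pd.read_csv(os.path.join(mtxdir, "cells.tsv"), sep="\t")
    obs = cells.set_index(cells.columns[0])
    obs.index = obs.index.astype(str)
    obs = obs.loc[bars[0].astype(str)]
    var_index = pd.Index(feats[0].astype(str).to_numpy())
    var_index.name = None
    obs.index = pd.Index(obs.index.astype(str).to_numpy())
    adata = ad.AnnData(X=x.T.tocsr(), obs=obs,
                       var=pd.DataFrame(index=var_index))
    adata.obs_names = bars[0].astype(str).tolist()
    adata.write_h5ad(h5ad_path)


if __name__ == "__main__":
    mode = sys.argv[1]
    if mode == "to-mtx":
        to_mtx(sys.argv[2], sys.argv[3])
    elif mode == "to-h5ad":
        to_h5ad(sys.argv[2], sys.argv[3])
    else:
        sys.exit("unknown mode: " + mode)
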