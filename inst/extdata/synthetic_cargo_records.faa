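>synMLS2 synthetic stand-in, malate synthase-like PTS2 cargo
MGSTADENPRIDSLGQHLADENPGSTADENPGSTADENPGSTADENPGSTADENPGSTA
>synPKT synthetic stand-in, 3-ketoacyl-CoA thiolase-like PTS2 cargo
MGSTADENPGSRLDSLGQHLSTCDENPGSTADENPGSTADENPGSTADENPGSTADENPG
>synHIT1 synthetic stand-in, histidine triad-like PTS2 cargo
MGSRLDSLGQHLSTCDENPGSTADENPGSTADENPGSTADENPGSTADENPGSTA
>synEMB8 synthetic stand-in, alpha/beta hydrolase-like PTS2+PTS1 cargo
MGSTADENPGSTADENPGSTADENPGSTADENPGRLDSLGQQLTADENPGSTADENPGST
ADESRL
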