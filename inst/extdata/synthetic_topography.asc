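ncols 16
nrows 12
xllcorner 0
yllcorner 40
cellsize 1
NODATA_value -9999
-30 80 -40 120 120 120 120 120 120 120 120 120 120 120 120 120
-30 -40 -40 120 120 120 120 120 120 120 120 120 120 120 120 120
-30 120 120 120 120 120 120 120 120 120 120 120 120 120 120 120
-30 120 120 -20 -20 -20 120 120 120 120 120 120 120 120 120 120
-30 120 120 -20 -20 -20 120 120 120 120 120 120 120 120 120 120
-30 120 120 -20 -20 -20 120 120 120 120 120 120 120 120 120 120
-30 120 120 120 120 120 120 120 120 120 120 120 120 120 120 120
-30 120 120 120 120 120 120 120 120 120 120 120 120 120 120 120
-30 120 120 120 120 120 120 120 120 120 120 120 120 120 120 120
-30 120 120 120 120 120 120 120 120 120 120 120 120 -50 -50 -50
-30 120 120 120 120 120 120 120 120 120 120 120 120 -50 -50 -50
-30 120 120 120 120 120 120 120 120 120 120 120 120 -50 -50 -50
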