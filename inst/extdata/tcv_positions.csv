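x,y
-9,9
-3,9
3,9
9,9
-9,3
-3,3
3,3
9,3
-9,-3
-3,-3
3,-3
9,-3
-9,-9
-3,-9
3,-9
9,-9
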