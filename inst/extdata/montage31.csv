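"name","x","y"
"Fp1",-0.309016994374947,0.951056516295154
"Fp2",0.309016994374947,0.951056516295154
"F7",-0.809016994374947,0.587785252292473
"F3",-0.419546927366558,0.518097307637981
"Fz",0,0.5
"F4",0.419546927366558,0.518097307637981
"F8",0.809016994374947,0.587785252292473
"FC5",-0.736491225347792,0.282712493530181
"FC1",-0.251415744421884,0.251415744421884
"FCz",0,0.244444444444444
"FC2",0.251415744421884,0.251415744421884
"FC6",0.736491225347792,0.282712493530181
"T7",-1,6.12323399573677e-17
"C3",-0.5,3.06161699786838e-17
"Cz",0,0
"C4",0.5,3.06161699786838e-17
"T8",1,6.12323399573677e-17
"CP5",-0.736491225347792,-0.282712493530181
"CP1",-0.251415744421884,-0.251415744421884
"CPz",2.99358106458242e-17,-0.244444444444444
"CP2",0.251415744421884,-0.251415744421884
"CP6",0.736491225347792,-0.282712493530181
"P7",-0.809016994374947,-0.587785252292473
"P3",-0.419546927366558,-0.51809730763798
"Pz",6.12323399573677e-17,-0.5
"P4",0.419546927366558,-0.51809730763798
"P8",0.809016994374947,-0.587785252292473
"POz",9.11681506031919e-17,-0.744444444444444
"O1",-0.309016994374948,-0.951056516295154
"Oz",1.22464679914735e-16,-1
"O2",0.309016994374948,-0.951056516295154
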