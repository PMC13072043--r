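,glioma,meningioma,notumor,pituitary
glioma,237,55,0,8
meningioma,11,278,1,16
notumor,0,1,404,0
pituitary,0,0,1,299
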