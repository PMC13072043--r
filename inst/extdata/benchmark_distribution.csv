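class,train,test
glioma,1321,300
meningioma,1339,306
pituitary,1457,300
notumor,1595,405
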