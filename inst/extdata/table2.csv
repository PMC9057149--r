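site,d11,d22,d33,span,skew,iso,anisotropy,asymmetry
C21,325.5,165.8,143.1,182.4,-0.7,211.4,171.1,0.2
C3,300.3,145.2,118,182.3,-0.7,187.8,168.7,0.2
C5,309.1,143.3,61.9,247.2,-0.3,171.4,206.5,0.6
C1,269.1,161.2,34.7,234.3,0.1,155,-180.4,0.9
C2,218.5,137.7,40.9,177.6,0.1,132.4,-137.2,0.9
C4,198.9,132.9,47,151.9,0.1,126.3,-118.9,0.8
C9,127.7,115.1,66.2,61.5,0.6,103,-55.2,0.3
C17,101.2,92.5,81.4,19.8,0.1,91.7,-15.5,0.8
C16,102.3,63.6,58.8,48.5,-0.6,73.2,43.7,0.3
C22,103.2,62.1,38,64.3,-0.3,68.1,52.7,0.6
C13,81.4,50.6,19.9,61.4,0,50.6,46.1,1
C10,65.8,52.6,26.4,39.4,0.3,48.3,-32.8,0.6
C14,88,27.9,18.6,69.4,-0.7,44.8,64.8,0.2
C12,54.1,39.7,29.4,24.7,-0.2,41.1,19.5,0.8
C11,55.6,39.3,15,40.6,0.2,36.6,-32.4,0.7
C8,56.2,35.1,8.3,47.9,0.1,33.2,-37.4,0.8
C15,51.3,32.7,10.5,40.8,0.1,31.5,-31.5,0.9
C7,44.5,30.8,17.1,27.3,0,30.8,-20.5,1
C6,45.5,24,11.6,33.9,-0.3,27,27.7,0.7
C19,44.7,24.3,10.1,34.6,-0.2,26.4,27.5,0.8
C18,30,16.3,9.1,20.9,-0.3,18.5,17.3,0.6
C20,28.5,15.3,4.5,24,-0.1,16.1,18.6,0.9
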