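File type = "ooTextFile"
Object class = "TextGrid"

xmin = 0
xmax = 20
tiers? <exists>
size = 2
item []:
    item [1]:
        class = "IntervalTier"
        name = "D01A"
        xmin = 0
        xmax = 20
        intervals: size = 12
        intervals [1]:
            xmin = 0
            xmax = 2.085518262364
            text = ""
        intervals [2]:
            xmin = 2.085518262364
            xmax = 3.63578932448116
            text = "speech"
        intervals [3]:
            xmin = 3.63578932448116
            xmax = 3.84768705580953
            text = ""
        intervals [4]:
            xmin = 3.84768705580953
            xmax = 6.08265556996914
            text = "speech"
        intervals [5]:
            xmin = 6.08265556996914
            xmax = 6.42043009738388
            text = ""
        intervals [6]:
            xmin = 6.42043009738388
            xmax = 7.99104516782144
            text = "speech"
        intervals [7]:
            xmin = 7.99104516782144
            xmax = 8.90103143573944
            text = ""
        intervals [8]:
            xmin = 8.90103143573944
            xmax = 14.2719228525876
            text = "speech"
        intervals [9]:
            xmin = 14.2719228525876
            xmax = 16.9827347388791
            text = ""
        intervals [10]:
            xmin = 16.9827347388791
            xmax = 17.3509601081475
            text = "speech"
        intervals [11]:
            xmin = 17.3509601081475
            xmax = 19.2540493442233
            text = ""
        intervals [12]:
            xmin = 19.2540493442233
            xmax = 20
            text = "speech"
    item [2]:
        class = "IntervalTier"
        name = "D01B"
        xmin = 0
        xmax = 20
        intervals: size = 9
        intervals [1]:
            xmin = 0
            xmax = 0.641447681172037
            text = ""
        intervals [2]:
            xmin = 0.641447681172037
            xmax = 2.03514343664331
            text = "speech"
        intervals [3]:
            xmin = 2.03514343664331
            xmax = 8.25200417631303
            text = ""
        intervals [4]:
            xmin = 8.25200417631303
            xmax = 8.61426496141733
            text = "speech"
        intervals [5]:
            xmin = 8.61426496141733
            xmax = 15.4907517763092
            text = ""
        intervals [6]:
            xmin = 15.4907517763092
            xmax = 16.7125997515006
            text = "speech"
        intervals [7]:
            xmin = 16.7125997515006
            xmax = 17.7972989968542
            text = ""
        intervals [8]:
            xmin = 17.7972989968542
            xmax = 18.8091600645326
            text = "speech"
        intervals [9]:
            xmin = 18.8091600645326
            xmax = 20
            text = ""
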